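test_that("identical group counts give zero fold change and no DEG flags", {
  m <- matrix(rep(c(40, 90, 400), 6), 3)
  x <- toy_counts(m, genotype = rep(c("healthy", "c9"), each = 3))
  d <- estimate_dispersion(x, x$samples$genotype)
  de <- de_test(x, disease_contrast("whole_cell"), d)
  expect_equal(de$log2fc, rep(0, 3), tolerance = 1e-9)
  expect_false(any(de$is_deg))
})

test_that("type-I error of the QL test is nominal on null data", {
  x <- cached("null_toy", nb_toy(51, nf = 2000, phi = 0.1))
  d <- cached("null_toy_disp", estimate_dispersion(x, x$samples$genotype))
  de <- de_test(x, disease_contrast("whole_cell"), d)
  rate <- mean(de$p < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / nrow(de))
  expect_lt(abs(rate - 0.05), band)
  # q-values respect the BH relationship to p
  expect_true(all(de$q >= de$p - 1e-12))
})

test_that("planted two-fold changes at moderate depth are detected with high
           power and little bias", {
  nf <- 2000
  lfc <- numeric(nf); lfc[1:200] <- rep(c(-2, 2), 100)
  x <- nb_toy(52, nf = nf, mu_log2_range = c(7, 11), phi = 0.1, lfc = lfc)
  d <- estimate_dispersion(x, x$samples$genotype)
  de <- de_test(x, disease_contrast("whole_cell"), d)
  expect_gte(mean(de$is_deg[1:200]), 0.90)
  # fold-change recovery is nearly unbiased
  expect_lt(abs(mean(de$log2fc[1:200] * sign(lfc[1:200])) - 2), 0.1)
})

test_that("monotone thresholding: raising the FC cut never adds DEG flags", {
  x <- cached("null_toy", nb_toy(51, nf = 2000, phi = 0.1))
  d <- cached("null_toy_disp", estimate_dispersion(x, x$samples$genotype))
  de2 <- de_test(x, disease_contrast("whole_cell"), d, fc_threshold = 2)
  de3 <- de_test(x, disease_contrast("whole_cell"), d, fc_threshold = 3)
  expect_true(all(de2$is_deg[de3$is_deg]))
})

test_that("scale invariance: multiplying one sample's counts changes no
           fold change beyond numerical tolerance", {
  set.seed(53)
  m <- matrix(rnbinom(300 * 6, mu = 2^runif(300, 4, 9), size = 10), 300)
  x <- toy_counts(m, genotype = rep(c("healthy", "c9"), each = 3))
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  x2 <- toy_counts(m2, genotype = rep(c("healthy", "c9"), each = 3))

  run <- function(xx) {
    f <- rle_size_factors(xx)
    d <- estimate_dispersion(xx, xx$samples$genotype, factors = f)
    de_test(xx, disease_contrast("whole_cell"), d)
  }
  de1 <- run(x); de2 <- run(x2)
  # size factors absorb the scaling exactly on the fold-change scale
  expect_lt(max(abs(de1$log2fc - de2$log2fc)), 1e-6)
})

test_that("with dispersion fixed at zero the plain LRT matches a Poisson GLM
           reference", {
  set.seed(54)
  m <- matrix(rpois(50 * 6, 2^runif(50, 4, 8)), 50)
  x <- toy_counts(m, genotype = rep(c("healthy", "c9"), each = 3))
  lib <- colSums(m)
  fac <- lib / exp(mean(log(lib)))  # factors reproduce the library sizes
  d <- estimate_dispersion(x, x$samples$genotype, factors = fac)
  d$trend <- rep(0, nrow(d))
  de <- de_test(x, disease_contrast("whole_cell"), d, ql = FALSE)

  eff <- lib
  g <- factor(rep(c("a", "b"), each = 3))
  p_ref <- vapply(seq_len(nrow(m)), function(i) {
    fit1 <- glm(m[i, ] ~ g + offset(log(eff)), family = poisson())
    fit0 <- glm(m[i, ] ~ 1 + offset(log(eff)), family = poisson())
    stats::pchisq(fit0$deviance - fit1$deviance, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(de$p, p_ref, tolerance = 1e-6)
})

test_that("contrast construction rejects undersized or overlapping groups", {
  m <- matrix(rpois(40, 20), 10, 4)
  x <- toy_counts(m, genotype = c("healthy", "healthy", "healthy", "c9"))
  d0 <- estimate_dispersion(x, factor(c(1, 1, 1, 2), levels = c(1, 2)))
  expect_error(de_test(x, disease_contrast("whole_cell"), d0), ">= 2 samples")
  bad <- make_contrast("bad", a = list(genotype = "healthy"),
                       b = list(genotype = c("healthy", "c9")))
  expect_error(de_test(x, bad, d0), "overlap")
})

test_that("one-way ANOVA matches the squared two-sample t and aov to
           high precision", {
  set.seed(55)
  e <- matrix(rnorm(20 * 6, mean = 8), 20)
  g <- rep(c("a", "b"), each = 3)
  res <- anova_de(e, g, fc_pair = c("a", "b"))
  for (i in c(1, 7, 20)) {
    tt <- t.test(e[i, g == "b"], e[i, g == "a"], var.equal = TRUE)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-9)
  }
  # three groups against stats::aov
  g3 <- rep(c("a", "b", "c"), each = 3)
  e3 <- matrix(rnorm(10 * 9, mean = 5), 10)
  res3 <- anova_de(e3, g3, fc_pair = c("a", "c"))
  for (i in c(2, 9)) {
    ref <- summary(stats::aov(e3[i, ] ~ factor(g3)))[[1]]$`Pr(>F)`[1]
    expect_equal(res3$p[i], ref, tolerance = 1e-9)
  }
})

test_that("degenerate ANOVA features report p = 1 and zero fold change", {
  e <- rbind(rep(3.5, 6), rnorm(6))
  res <- anova_de(e, rep(c("a", "b"), each = 3))
  expect_equal(res$p[1], 1)
  expect_equal(res$log2fc[1], 0)
  expect_error(anova_de(e, c("a", "a", "a", "a", "a", "b")), "single sample")
})

test_that("BH adjustment handles the hand-worked step-up cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order-preserving in the ranking
  p <- c(0.001, 0.5, 0.02, 0.9)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")
})

test_that("gene rollup flags a gene when any isoform is significant", {
  de <- data.frame(feature_id = c("t1", "t2", "t3"),
                   log2fc = c(2, 0.1, -3), mean_log2cpm = 5,
                   p = c(0.01, 0.9, 0.001), q = c(0.02, 0.9, 0.003),
                   is_deg = c(TRUE, FALSE, TRUE))
  map <- c(t1 = "gA", t2 = "gA", t3 = "gB")
  roll <- rollup_genes(de, map)
  expect_identical(roll$is_deg[roll$gene_id == "gA"], TRUE)
  expect_equal(roll$n_features[roll$gene_id == "gA"], 2)
})
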