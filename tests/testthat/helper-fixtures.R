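# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# minimal count object from a bare matrix; metadata defaults are inert
toy_counts <- function(mat, genotype = NULL, treatment = NULL,
                       fraction = "whole_cell") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  n <- ncol(mat)
  sheet <- data.frame(
    sample_id = colnames(mat),
    genotype = genotype %||% rep("healthy", n),
    treatment = treatment %||% rep("ctrl_rnai", n),
    fraction = fraction,
    individual_id = colnames(mat),
    replicate = 1L,
    stringsAsFactors = FALSE)
  fdx_counts(mat, sheet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a 3 vs 3 single-fraction NB matrix with optional planted fold changes
nb_toy <- function(seed, nf = 2000, mu_log2_range = c(5, 10), phi = 0.1,
                   lfc = numeric(nf)) {
  set.seed(seed)
  mu <- 2^stats::runif(nf, mu_log2_range[1], mu_log2_range[2])
  mum <- outer(mu, rep(1, 6))
  mum[, 4:6] <- mum[, 4:6] * 2^lfc
  cnt <- matrix(stats::rnbinom(nf * 6, mu = mum, size = 1 / phi), nf)
  toy_counts(cnt, genotype = rep(c("healthy", "c9"), each = 3))
}

de_pipeline <- function(x, contrast) {
  xf <- filter_low_counts(x)
  d <- estimate_dispersion(
    xf, interaction(xf$samples$genotype, xf$samples$treatment))
  de_test(xf, contrast, d)
}

default_sim <- function() {
  cached("sim_default", simulate_fractionated_counts(sim_config(seed = 101)))
}

default_de <- function(which) {
  ds <- default_sim()
  switch(which,
    disease_wct = cached("de_dis_w",
      de_pipeline(ds$wct, disease_contrast("whole_cell"))),
    treated_wct = cached("de_trt_w",
      de_pipeline(ds$wct, treated_contrast("c9", "whole_cell"))),
    treated_cyt = cached("de_trt_c",
      de_pipeline(ds$cyt, treated_contrast("c9", "cytoplasmic"))),
    stop("unknown fixture"))
}

small_exon_sim <- function() {
  cached("sim_small_exon",
         simulate_fractionated_counts(sim_config(n_features = 150, seed = 23,
                                                 n_disease_de = 10,
                                                 n_treatment_reversed = 3,
                                                 n_treatment_concordant = 1,
                                                 n_treatment_only = 2,
                                                 n_export_altered = 5,
                                                 n_exon_usage_altered = 10)))
}

two_species_fixture <- function() {
  cached("two_species", {
    cfg_a <- sim_config(n_features = 1200, seed = 201,
                        library_size_range = c(4e6, 6e6),
                        disease_log2fc_range = c(2, 3),
                        treatment_log2fc_range = c(2, 3))
    cfg_b <- sim_config(n_features = 1200, seed = 202,
                        library_size_range = c(4e6, 6e6),
                        disease_log2fc_range = c(2, 3),
                        treatment_log2fc_range = c(2, 3))
    ts <- simulate_two_species(cfg_a, cfg_b, n_conserved = 5, n_opposite = 3,
                               n_reciprocal = 2)
    ts$de_a_dis <- de_pipeline(ts$a$wct, disease_contrast("whole_cell"))
    ts$de_b_dis <- de_pipeline(ts$b$wct, disease_contrast("whole_cell"))
    ts$sig_a <- build_signature(
      ts$de_a_dis, de_pipeline(ts$a$wct, treated_contrast("c9", "whole_cell")))
    ts$sig_b <- build_signature(
      ts$de_b_dis, de_pipeline(ts$b$wct, treated_contrast("c9", "whole_cell")))
    ts
  })
}
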