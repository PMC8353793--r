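test_that("identical config and seed give bit-identical datasets", {
  cfg <- sim_config(n_features = 400, seed = 5)
  a <- simulate_fractionated_counts(cfg)
  b <- simulate_fractionated_counts(cfg)
  expect_identical(a$wct$counts, b$wct$counts)
  expect_identical(a$cyt$counts, b$cyt$counts)
  expect_identical(a$truth, b$truth)
})

test_that("all-zero effect config produces an all-null truth table", {
  cfg <- sim_config(n_features = 80, seed = 3, n_disease_de = 0,
                    n_treatment_reversed = 0, n_treatment_concordant = 0,
                    n_treatment_only = 0, n_export_altered = 0,
                    n_exon_usage_altered = 0)
  ds <- simulate_fractionated_counts(cfg)
  expect_true(all(ds$truth$disease_log2fc == 0))
  expect_true(all(ds$truth$treatment_log2fc == 0))
  expect_true(all(ds$truth$export_log2fc == 0))
  expect_false(any(ds$truth$exon_usage_altered))
})

test_that("config validation rejects impossible requests", {
  expect_error(sim_config(n_features = 10, n_disease_de = 8,
                          n_treatment_only = 2, n_export_altered = 1),
               "exceed")
  expect_error(sim_config(n_treatment_reversed = 40, n_disease_de = 30),
               "exceed")
  expect_error(sim_config(cytoplasmic_fraction_range = c(0, 0.5)), "0, 1")
  expect_error(sim_config(library_size_range = c(2e6, 1e6)), "ordered")
})

test_that("reversed features have treatment sign opposite to disease sign", {
  ds <- default_sim()
  tr <- ds$truth
  rev <- tr$disease_log2fc != 0 & tr$treatment_log2fc != 0 &
    sign(tr$treatment_log2fc) == -sign(tr$disease_log2fc)
  expect_equal(sum(rev), ds$config$n_treatment_reversed)
  con <- tr$disease_log2fc != 0 & tr$treatment_log2fc != 0 &
    sign(tr$treatment_log2fc) == sign(tr$disease_log2fc)
  expect_equal(sum(con), ds$config$n_treatment_concordant)
})

test_that("whole-cell means match construction and export shifts the
           cytoplasm by 2^lfc * f", {
  # constant library and no jitter so the expected mean is in closed form;
  # many individuals give hundreds of replicate draws per condition
  cfg <- sim_config(n_features = 60, n_individuals_per_genotype = 100,
                    seed = 17, individual_sd = 0,
                    dispersion_meanlog = log(0.05), dispersion_sdlog = 0,
                    library_size_range = c(1e6, 1e6),
                    n_disease_de = 0, n_treatment_reversed = 0,
                    n_treatment_concordant = 0, n_treatment_only = 0,
                    n_export_altered = 10, export_log2fc_range = c(1, 1),
                    n_exon_usage_altered = 0)
  ds <- simulate_fractionated_counts(cfg)
  tr <- ds$truth
  expected <- 2^tr$baseline_log2mean / sum(2^tr$baseline_log2mean) * 1e6

  # construction fidelity on whole-cell means (srsf1 columns carry no
  # whole-cell effect here, so all 400 samples are replicates)
  emp <- rowMeans(ds$wct$counts)
  hi <- expected >= 100
  expect_true(all(abs(emp[hi] / expected[hi] - 1) < 0.05))

  # export features: CyT/WCT mean ratio in treated samples is 2 * f
  srsf1 <- ds$wct$samples$treatment == "srsf1_rnai"   # 200 samples
  idx <- which(tr$export_log2fc == 1 & expected >= 100)
  ratio <- rowMeans(ds$cyt$counts[idx, srsf1, drop = FALSE]) /
    rowMeans(ds$wct$counts[idx, srsf1, drop = FALSE])
  expect_true(all(abs(ratio / (2 * tr$cyt_fraction[idx]) - 1) < 0.10))
  # and untreated samples show the bare cytoplasmic fraction
  ctrl <- !srsf1
  ratio0 <- rowMeans(ds$cyt$counts[idx, ctrl, drop = FALSE]) /
    rowMeans(ds$wct$counts[idx, ctrl, drop = FALSE])
  expect_true(all(abs(ratio0 / tr$cyt_fraction[idx] - 1) < 0.10))
})

test_that("exon counts sum exactly to gene counts in every sample", {
  ds <- small_exon_sim()
  ex <- simulate_exon_counts(ds)
  sums <- rowsum(ex$counts, ex$exons$gene_id)
  expect_identical(sums[rownames(ds$wct$counts), ], ds$wct$counts)
})

test_that("planted exon-usage shift is recovered empirically", {
  ds <- small_exon_sim()
  ex <- simulate_exon_counts(ds)
  et <- attr(ex, "exon_truth")
  s <- attr(ex, "samples")
  first_exon <- !duplicated(ex$exons$gene_id)
  gene_tot <- rowsum(ex$counts, ex$exons$gene_id)
  alt <- which(et$altered)
  for (g in alt) {
    gid <- et$gene_id[g]
    e1 <- which(first_exon & ex$exons$gene_id == gid)
    for (geno in c("healthy", "c9")) {
      jj <- s$genotype == geno
      tot <- sum(gene_tot[gid, jj])
      if (tot < 1e3) next  # binomial bound needs enough reads
      pi_hat <- sum(ex$counts[e1, jj]) / tot
      pi_true <- if (geno == "healthy") et$usage_healthy[g] else et$usage_c9[g]
      expect_lt(abs(pi_hat - pi_true), 0.05)
    }
  }
})

test_that("two-species generator is deterministic and links the planted
           pair classes", {
  mk <- function(seed) sim_config(n_features = 300, seed = seed,
                                  n_disease_de = 40, n_treatment_reversed = 10,
                                  n_treatment_concordant = 2,
                                  n_treatment_only = 5, n_export_altered = 10,
                                  n_exon_usage_altered = 5)
  cfg_a <- mk(31)
  cfg_b <- mk(32)
  t1 <- simulate_two_species(cfg_a, cfg_b, n_conserved = 4, n_opposite = 2,
                             n_reciprocal = 1)
  t2 <- simulate_two_species(cfg_a, cfg_b, n_conserved = 4, n_opposite = 2,
                             n_reciprocal = 1)
  expect_identical(t1$homology, t2$homology)
  expect_identical(t1$a$wct$counts, t2$a$wct$counts)

  pt <- t1$pair_truth
  ta <- t1$a$truth; tb <- t1$b$truth
  for (i in which(pt$class == "conserved")) {
    sa <- sign(ta$disease_log2fc[match(pt$gene_a[i], ta$feature_id)])
    sb <- sign(tb$disease_log2fc[match(pt$gene_b[i], tb$feature_id)])
    expect_identical(sa, sb)
  }
  for (i in which(pt$class == "opposite")) {
    sa <- sign(ta$disease_log2fc[match(pt$gene_a[i], ta$feature_id)])
    sb <- sign(tb$disease_log2fc[match(pt$gene_b[i], tb$feature_id)])
    expect_identical(sa, -sb)
  }
  null_genes_a <- pt$gene_a[pt$class == "null"]
  expect_true(all(ta$disease_log2fc[match(null_genes_a, ta$feature_id)] == 0))
  expect_error(simulate_two_species(cfg_a, cfg_b, n_conserved = 500),
               "not enough")
})

test_that("a dataset writes and re-reads through the TSV interface", {
  ds <- small_exon_sim()
  td <- withr::local_tempdir()
  write_sim_dataset(ds, td, exons = simulate_exon_counts(ds))
  back <- read_count_matrix(file.path(td, "wct.tsv"),
                            file.path(td, "samples_wct.tsv"))
  expect_identical(back$counts, ds$wct$counts)
  exb <- read_exon_counts(file.path(td, "exons.tsv"))
  expect_equal(sum(exb$counts), sum(ds$wct$counts))
})
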