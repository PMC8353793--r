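#' Simulation configuration
#'
#' Parameters of the synthetic fractionated-transcriptome generator.  The
#' defaults emulate a patient-derived-neuron study design: two genotypes
#' (healthy, c9) x two treatments (control RNAi, SRSF1 RNAi) x two
#' fractions (whole-cell, cytoplasmic), three individuals per genotype,
#' negative-binomial counts with a lognormal dispersion distribution,
#' per-individual baseline jitter, and planted disease, treatment-reversal
#' and nuclear-export effects.
#'
#' @param n_features Number of simulated features (transcripts).
#' @param n_individuals_per_genotype Individuals per genotype; each yields
#'   samples under both treatments and both fractions.
#' @param seed Integer seed; identical configs give bit-identical datasets.
#' @param baseline_logmean Mean and sd of the per-feature baseline log2
#'   relative expression.
#' @param dispersion_meanlog,dispersion_sdlog Lognormal parameters of the
#'   per-feature NB dispersion phi (variance = mu + phi mu^2).
#' @param library_size_range Range of expected whole-cell counts per sample.
#' @param individual_sd SD (log2 units) of per-individual per-feature
#'   baseline jitter, shared by all samples of one individual.
#' @param n_disease_de Features with a planted disease (c9 vs healthy)
#'   effect.
#' @param disease_log2fc_range Magnitude range of disease log2 fold changes
#'   (signs random).
#' @param n_treatment_reversed Subset of disease features whose planted
#'   treatment effect has the opposite sign (reversal under SRSF1 RNAi).
#' @param n_treatment_concordant Subset of disease features whose planted
#'   treatment effect has the same sign as the disease effect.
#' @param n_treatment_only Features with a treatment effect but no disease
#'   effect.
#' @param treatment_log2fc_range Magnitude range of treatment effects.
#' @param n_export_altered Features with a planted cytoplasm-only (export)
#'   shift, active in SRSF1-RNAi-treated samples; disjoint from the disease
#'   and treatment sets.
#' @param export_log2fc_range Magnitude range of export effects.
#' @param cytoplasmic_fraction_range Range of the per-feature cytoplasmic
#'   fraction f in (0, 1].
#' @param effect_baseline_quantile Effects are planted among features whose
#'   baseline exceeds this quantile, so planted features are quantifiable.
#' @param n_exons_per_gene_range Range of exon counts per gene for the exon
#'   simulator.
#' @param n_exon_usage_altered Genes with a planted exon-usage shift.
#' @param exon_usage_from,exon_usage_to Usage proportion of the designated
#'   exon in the healthy and c9 genotypes for altered genes.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_features = 2000,
                       n_individuals_per_genotype = 3,
                       seed = 1,
                       baseline_logmean = c(5, 2),
                       dispersion_meanlog = log(0.1),
                       dispersion_sdlog = 0.5,
                       library_size_range = c(1e6, 2e6),
                       individual_sd = 0.3,
                       n_disease_de = 100,
                       disease_log2fc_range = c(1.5, 3),
                       n_treatment_reversed = 30,
                       n_treatment_concordant = 5,
                       n_treatment_only = 20,
                       treatment_log2fc_range = c(1.5, 3),
                       n_export_altered = 50,
                       export_log2fc_range = c(2, 3),
                       cytoplasmic_fraction_range = c(0.2, 0.8),
                       effect_baseline_quantile = 0.5,
                       n_exons_per_gene_range = c(2, 8),
                       n_exon_usage_altered = 20,
                       exon_usage_from = 0.5,
                       exon_usage_to = 0.1) {
  cfg <- as.list(environment())
  if (cfg$n_features < 1 || cfg$n_individuals_per_genotype < 1)
    stop("n_features and n_individuals_per_genotype must be positive")
  if (cfg$dispersion_sdlog < 0) stop("dispersion_sdlog must be >= 0")
  if (cfg$n_treatment_reversed + cfg$n_treatment_concordant > cfg$n_disease_de)
    stop("reversed + concordant treatment features cannot exceed n_disease_de")
  if (cfg$n_disease_de + cfg$n_treatment_only + cfg$n_export_altered >
      cfg$n_features)
    stop("planted effect counts exceed n_features")
  for (r in c("baseline_logmean", "library_size_range", "disease_log2fc_range",
              "treatment_log2fc_range", "export_log2fc_range",
              "cytoplasmic_fraction_range", "n_exons_per_gene_range")) {
    if (length(cfg[[r]]) != 2) stop(r, " must have length 2")
  }
  ordered_rng <- c("library_size_range", "disease_log2fc_range",
                   "treatment_log2fc_range", "export_log2fc_range",
                   "cytoplasmic_fraction_range", "n_exons_per_gene_range")
  for (r in ordered_rng) if (cfg[[r]][1L] > cfg[[r]][2L])
    stop(r, " must be ordered (lo, hi)")
  f <- cfg$cytoplasmic_fraction_range
  if (f[1L] <= 0 || f[2L] > 1) stop("cytoplasmic_fraction_range must lie in (0, 1]")
  if (cfg$n_exons_per_gene_range[1L] < 2)
    stop("genes need at least 2 exons")
  structure(cfg, class = "sim_config")
}

sub_seed <- function(seed, k) (as.integer(seed) + k) %% 2147483647L

#' Simulate a paired whole-cell / cytoplasmic count dataset
#'
#' Draws a truth table (baselines, dispersions, cytoplasmic fractions,
#' planted effects), builds the latent expected whole-cell mean for every
#' feature and sample — baseline plus individual jitter plus disease effect
#' in c9 samples plus treatment effect in SRSF1-RNAi samples, scaled to the
#' sample's library size — and couples the cytoplasmic mean to it as
#' \code{f_g} times the whole-cell mean times \code{2^export_log2fc} in
#' export-affected samples.  Counts are NB draws at the feature's
#' dispersion.  Export effects never touch whole-cell means.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Object of class \code{fdx_sim}: list with \code{wct} and
#'   \code{cyt} (\code{fdx_counts} sharing features and design),
#'   \code{truth} (per-feature data frame with \code{feature_id},
#'   \code{baseline_log2mean}, \code{dispersion}, \code{cyt_fraction},
#'   \code{disease_log2fc}, \code{treatment_log2fc}, \code{export_log2fc},
#'   \code{exon_usage_altered}), and \code{config}.
#' @export
simulate_fractionated_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  nf <- cfg$n_features
  nind <- cfg$n_individuals_per_genotype

  set.seed(sub_seed(cfg$seed, 0L))
  feature_id <- sprintf("FTR%05d", seq_len(nf))
  baseline <- stats::rnorm(nf, cfg$baseline_logmean[1L], cfg$baseline_logmean[2L])
  phi <- stats::rlnorm(nf, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  f_cyt <- stats::runif(nf, cfg$cytoplasmic_fraction_range[1L],
                        cfg$cytoplasmic_fraction_range[2L])

  # plant effects among quantifiable (abundant) features, disjoint sets
  eligible <- which(baseline >= stats::quantile(baseline,
                                               cfg$effect_baseline_quantile))
  n_eff <- cfg$n_disease_de + cfg$n_treatment_only + cfg$n_export_altered
  if (length(eligible) < n_eff)
    stop("not enough features above effect_baseline_quantile to plant effects")
  picked <- sample(eligible, n_eff)
  idx_disease <- picked[seq_len(cfg$n_disease_de)]
  idx_trt_only <- picked[cfg$n_disease_de + seq_len(cfg$n_treatment_only)]
  idx_export <- picked[cfg$n_disease_de + cfg$n_treatment_only +
                         seq_len(cfg$n_export_altered)]
  idx_reversed <- idx_disease[seq_len(cfg$n_treatment_reversed)]
  idx_concordant <- idx_disease[cfg$n_treatment_reversed +
                                  seq_len(cfg$n_treatment_concordant)]

  disease_fc <- numeric(nf)
  treatment_fc <- numeric(nf)
  export_fc <- numeric(nf)
  rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  disease_fc[idx_disease] <- rsign(length(idx_disease)) *
    stats::runif(length(idx_disease), cfg$disease_log2fc_range[1L],
                 cfg$disease_log2fc_range[2L])
  treatment_fc[idx_reversed] <- -sign(disease_fc[idx_reversed]) *
    stats::runif(length(idx_reversed), cfg$treatment_log2fc_range[1L],
                 cfg$treatment_log2fc_range[2L])
  treatment_fc[idx_concordant] <- sign(disease_fc[idx_concordant]) *
    stats::runif(length(idx_concordant), cfg$treatment_log2fc_range[1L],
                 cfg$treatment_log2fc_range[2L])
  treatment_fc[idx_trt_only] <- rsign(length(idx_trt_only)) *
    stats::runif(length(idx_trt_only), cfg$treatment_log2fc_range[1L],
                 cfg$treatment_log2fc_range[2L])
  export_fc[idx_export] <- rsign(length(idx_export)) *
    stats::runif(length(idx_export), cfg$export_log2fc_range[1L],
                 cfg$export_log2fc_range[2L])

  # exon-usage flags (used by simulate_exon_counts); any gene may carry one
  exon_altered <- logical(nf)
  if (cfg$n_exon_usage_altered > 0)
    exon_altered[sample(eligible, cfg$n_exon_usage_altered)] <- TRUE

  genotype_of_ind <- rep(c("healthy", "c9"), each = nind)
  ind_ids <- c(sprintf("H%02d", seq_len(nind)), sprintf("C%02d", seq_len(nind)))
  jitter <- matrix(stats::rnorm(nf * length(ind_ids), 0, cfg$individual_sd),
                   nrow = nf)

  design <- expand.grid(treatment = TREATMENT_LEVELS,
                        ind = seq_along(ind_ids),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ns <- nrow(design)  # per fraction
  lib <- stats::runif(ns, cfg$library_size_range[1L], cfg$library_size_range[2L])

  sheet <- function(fraction) {
    data.frame(
      sample_id = sprintf("%s_%s_%s", ind_ids[design$ind], design$treatment,
                          substr(fraction, 1, 3)),
      genotype = genotype_of_ind[design$ind],
      treatment = design$treatment,
      fraction = fraction,
      individual_id = ind_ids[design$ind],
      replicate = 1L,
      stringsAsFactors = FALSE)
  }
  sheet_wct <- sheet("whole_cell")
  sheet_cyt <- sheet("cytoplasmic")

  # latent whole-cell means, columns scaled to library size
  mu_wct <- matrix(0, nf, ns)
  mu_cyt <- matrix(0, nf, ns)
  for (j in seq_len(ns)) {
    ind <- design$ind[j]
    lg <- baseline + jitter[, ind] +
      disease_fc * (genotype_of_ind[ind] == "c9") +
      treatment_fc * (design$treatment[j] == "srsf1_rnai")
    rel <- 2^lg
    mu_wct[, j] <- rel / sum(rel) * lib[j]
    exp_active <- design$treatment[j] == "srsf1_rnai"
    mu_cyt[, j] <- f_cyt * mu_wct[, j] * 2^(export_fc * exp_active)
  }

  draw <- function(mu, seed_off) {
    set.seed(sub_seed(cfg$seed, seed_off))
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = rep(1 / phi, ncol(mu))),
                  nrow = nrow(mu))
    cnt
  }
  cnt_wct <- draw(mu_wct, 1L)
  cnt_cyt <- draw(mu_cyt, 2L)
  dimnames(cnt_wct) <- list(feature_id, sheet_wct$sample_id)
  dimnames(cnt_cyt) <- list(feature_id, sheet_cyt$sample_id)

  truth <- data.frame(feature_id = feature_id,
                      baseline_log2mean = baseline, dispersion = phi,
                      cyt_fraction = f_cyt, disease_log2fc = disease_fc,
                      treatment_log2fc = treatment_fc,
                      export_log2fc = export_fc,
                      exon_usage_altered = exon_altered,
                      stringsAsFactors = FALSE)

  structure(list(wct = fdx_counts(cnt_wct, sheet_wct),
                 cyt = fdx_counts(cnt_cyt, sheet_cyt),
                 truth = truth, config = cfg),
            class = "fdx_sim")
}

#' Simulate exon-level counts for a dataset
#'
#' Splits each gene's whole-cell count across a fixed per-gene proportion
#' vector by multinomial draws, so exon counts sum exactly to the gene
#' count in every sample.  For genes flagged \code{exon_usage_altered} in
#' the truth table, the first exon's usage proportion is
#' \code{exon_usage_from} in healthy samples and \code{exon_usage_to} in c9
#' samples (remaining exons share the rest proportionally).
#'
#' @param dataset An \code{fdx_sim}.
#' @param config The \code{sim_config} (defaults to the dataset's own).
#' @return An \code{fdx_exons} object over the whole-cell samples; the
#'   per-gene designated-exon truth is attached as attribute
#'   \code{exon_truth}.
#' @export
simulate_exon_counts <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "fdx_sim"))
  cfg <- config
  set.seed(sub_seed(cfg$seed, 3L))
  counts <- dataset$wct$counts
  samples <- dataset$wct$samples
  nf <- nrow(counts)
  n_ex <- sample(seq(cfg$n_exons_per_gene_range[1L],
                     cfg$n_exons_per_gene_range[2L]), nf, replace = TRUE)
  altered <- dataset$truth$exon_usage_altered
  if (any(altered & n_ex < 2)) stop("exon-usage-altered gene with < 2 exons")

  gene_ids <- rownames(counts)
  is_c9 <- samples$genotype == "c9"
  exon_rows <- vector("list", nf)
  truth_rows <- vector("list", nf)
  for (g in seq_len(nf)) {
    k <- n_ex[g]
    base_pr <- stats::rgamma(k, shape = 2)
    base_pr <- base_pr / sum(base_pr)
    pr_h <- pr_c <- base_pr
    if (altered[g]) {
      rest <- base_pr[-1L] / sum(base_pr[-1L])
      pr_h <- c(cfg$exon_usage_from, (1 - cfg$exon_usage_from) * rest)
      pr_c <- c(cfg$exon_usage_to, (1 - cfg$exon_usage_to) * rest)
    }
    m <- matrix(0, k, ncol(counts))
    for (j in seq_len(ncol(counts))) {
      pr <- if (is_c9[j]) pr_c else pr_h
      m[, j] <- stats::rmultinom(1L, size = counts[g, j], prob = pr)
    }
    exon_rows[[g]] <- m
    truth_rows[[g]] <- data.frame(gene_id = gene_ids[g], n_exons = k,
                                  altered = altered[g],
                                  usage_healthy = pr_h[1L],
                                  usage_c9 = pr_c[1L],
                                  stringsAsFactors = FALSE)
  }
  exon_counts <- do.call(rbind, exon_rows)
  gene_of_exon <- rep(gene_ids, n_ex)
  exon_id <- paste0(gene_of_exon, ":E",
                    unlist(lapply(n_ex, seq_len), use.names = FALSE))
  colnames(exon_counts) <- colnames(counts)
  out <- fdx_exons(exon_id, gene_of_exon, exon_counts)
  attr(out, "exon_truth") <- do.call(rbind, truth_rows)
  attr(out, "samples") <- samples
  out
}

#' Simulate a paired two-species experiment with a homology table
#'
#' Generates two independent datasets (e.g. a human-like and a fly-like
#' transcriptome) and links features across them: \code{n_conserved} pairs
#' share the planted disease-effect sign (of which \code{n_reciprocal} are
#' reversal features in both species, i.e. disease and treatment signs
#' opposite within each species and disease signs matching across), and
#' \code{n_opposite} pairs have opposing disease signs.  Additional null
#' features are linked so the table is not all signal.
#'
#' @param config_a,config_b Configurations for the two species.
#' @param n_conserved Pairs with matching disease-effect sign.
#' @param n_opposite Pairs with opposing disease-effect sign.
#' @param n_reciprocal Conserved pairs that are treatment-reversed in both
#'   species (must not exceed \code{n_conserved}).
#' @param n_null_pairs Pairs linking effect-free features.
#' @return List with \code{a}, \code{b} (\code{fdx_sim}), \code{homology}
#'   (two-column data frame), and \code{pair_truth} (per-pair class:
#'   \code{conserved}/\code{opposite}/\code{null}, and \code{reciprocal}).
#' @export
simulate_two_species <- function(config_a, config_b, n_conserved = 5,
                                 n_opposite = 3, n_reciprocal = 0,
                                 n_null_pairs = 50) {
  if (n_reciprocal > n_conserved) stop("n_reciprocal cannot exceed n_conserved")
  ds_a <- simulate_fractionated_counts(config_a)
  ds_b <- simulate_fractionated_counts(config_b)

  pick_pairs <- function(ta, tb, n, same_sign, reversed) {
    sel <- function(tt) {
      i <- which(tt$disease_log2fc != 0 &
                   (if (reversed) tt$treatment_log2fc != 0 &
                      sign(tt$treatment_log2fc) == -sign(tt$disease_log2fc)
                    else tt$treatment_log2fc == 0))
      split(i, sign(tt$disease_log2fc[i]))
    }
    sa <- sel(ta); sb <- sel(tb)
    pairs <- matrix(integer(0), ncol = 2)
    for (s in c("-1", "1")) {
      s_b <- if (same_sign) s else setdiff(c("-1", "1"), s)
      na <- length(sa[[s]]); nb <- length(sb[[s_b]])
      k <- min(na, nb, n - nrow(pairs))
      if (k > 0) {
        pairs <- rbind(pairs, cbind(sa[[s]][seq_len(k)], sb[[s_b]][seq_len(k)]))
        sa[[s]] <- sa[[s]][-seq_len(k)]
        sb[[s_b]] <- sb[[s_b]][-seq_len(k)]
      }
    }
    if (nrow(pairs) < n)
      stop("not enough planted effect features to build the requested pairs")
    pairs
  }

  used_a <- integer(0); used_b <- integer(0)
  ta <- ds_a$truth; tb <- ds_b$truth

  take <- function(n, same_sign, reversed) {
    ta2 <- ta; tb2 <- tb
    ta2$disease_log2fc[used_a] <- 0; tb2$disease_log2fc[used_b] <- 0
    if (n == 0) return(matrix(integer(0), ncol = 2))
    pick_pairs(ta2, tb2, n, same_sign, reversed)
  }

  p_rec <- take(n_reciprocal, same_sign = TRUE, reversed = TRUE)
  used_a <- c(used_a, p_rec[, 1L]); used_b <- c(used_b, p_rec[, 2L])
  p_con <- take(n_conserved - n_reciprocal, same_sign = TRUE, reversed = FALSE)
  used_a <- c(used_a, p_con[, 1L]); used_b <- c(used_b, p_con[, 2L])
  p_opp <- take(n_opposite, same_sign = FALSE, reversed = FALSE)
  used_a <- c(used_a, p_opp[, 1L]); used_b <- c(used_b, p_opp[, 2L])

  null_a <- which(ta$disease_log2fc == 0 & ta$treatment_log2fc == 0 &
                    ta$export_log2fc == 0)
  null_b <- which(tb$disease_log2fc == 0 & tb$treatment_log2fc == 0 &
                    tb$export_log2fc == 0)
  k <- min(n_null_pairs, length(null_a), length(null_b))
  p_null <- cbind(null_a[seq_len(k)], null_b[seq_len(k)])

  all_pairs <- rbind(p_rec, p_con, p_opp, p_null)
  cls <- c(rep("conserved", nrow(p_rec) + nrow(p_con)),
           rep("opposite", nrow(p_opp)), rep("null", nrow(p_null)))
  rec <- c(rep(TRUE, nrow(p_rec)), rep(FALSE, nrow(p_con) + nrow(p_opp) +
                                         nrow(p_null)))
  homology <- data.frame(gene_a = ta$feature_id[all_pairs[, 1L]],
                         gene_b = tb$feature_id[all_pairs[, 2L]],
                         stringsAsFactors = FALSE)
  pair_truth <- cbind(homology, class = cls, reciprocal = rec,
                      stringsAsFactors = FALSE)
  list(a = ds_a, b = ds_b, homology = homology, pair_truth = pair_truth)
}

#' Write every component of a simulated dataset to a directory
#'
#' Emits \code{wct.tsv}, \code{cyt.tsv}, \code{samples_wct.tsv},
#' \code{samples_cyt.tsv}, \code{truth.tsv} and, when exons are supplied,
#' \code{exons.tsv}.
#'
#' @param dataset An \code{fdx_sim}.
#' @param outdir Output directory (created if needed).
#' @param exons Optional \code{fdx_exons}.
#' @return Invisibly, \code{outdir}.
#' @export
write_sim_dataset <- function(dataset, outdir, exons = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(dataset$wct, file.path(outdir, "wct.tsv"),
                     file.path(outdir, "samples_wct.tsv"))
  write_count_matrix(dataset$cyt, file.path(outdir, "cyt.tsv"),
                     file.path(outdir, "samples_cyt.tsv"))
  write_results_table(dataset$truth, file.path(outdir, "truth.tsv"),
                      seed = dataset$config$seed)
  if (!is.null(exons)) write_exon_counts(exons, file.path(outdir, "exons.tsv"))
  invisible(outdir)
}
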