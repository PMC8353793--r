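#' Filter features with low counts
#'
#' Retains features whose counts-per-million (computed from raw library
#' sizes) reach \code{min_cpm} in at least \code{min_samples} samples; the
#' boundary is inclusive.  The default (CPM >= 2 in >= 2 samples) is the
#' usual screen applied before dispersion estimation.
#'
#' @param x An \code{fdx_counts} object.
#' @param min_cpm Minimum counts-per-million (inclusive).
#' @param min_samples Minimum number of samples reaching \code{min_cpm}.
#' @return An \code{fdx_counts} restricted to the retained features; the
#'   sample set is unchanged.
#' @export
filter_low_counts <- function(x, min_cpm = 2, min_samples = 2) {
  stopifnot(inherits(x, "fdx_counts"))
  lib <- colSums(x$counts)
  if (any(lib <= 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(x$counts)[lib <= 0], collapse = ", "))
  cpm <- sweep(x$counts, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep))
    stop("all features removed by the low-count filter; review min_cpm/min_samples")
  x[keep, ]
}

#' Relative log expression (RLE) size factors
#'
#' Median-of-ratios normalisation: each sample's factor is the median, over
#' features with strictly positive counts in every sample, of the ratio of
#' that sample's count to the feature's geometric mean.  Factors are
#' rescaled to have geometric mean 1.  When no feature is positive in all
#' samples the total library size is used as a fallback, with a warning.
#'
#' @param x An \code{fdx_counts} object.
#' @return Numeric vector of positive size factors, one per sample, named by
#'   sample id, with geometric mean 1.
#' @export
rle_size_factors <- function(x) {
  stopifnot(inherits(x, "fdx_counts"))
  counts <- x$counts
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (any(ref)) {
    logc <- log(counts[ref, , drop = FALSE])
    geo <- rowMeans(logc)
    s <- apply(exp(logc - geo), 2L, stats::median)
  } else {
    warning("no feature has positive counts in all samples; ",
            "falling back to library-size factors")
    s <- colSums(counts)
  }
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(counts)
  if (any(!is.finite(s) | s <= 0)) stop("non-finite or non-positive size factor")
  s
}

# Effective per-sample sequencing depth.  RLE size factors are
# median-of-ratios factors proportional to the sample's depth (geometric
# mean 1), so the absolute effective depth is factor x geometric-mean
# library size; without factors the raw library size is used.
eff_libsize <- function(x, factors = NULL) {
  lib <- colSums(x$counts)
  if (is.null(factors)) return(lib)
  if (length(factors) != ncol(x$counts)) stop("size factors do not match samples")
  factors * exp(mean(log(lib)))
}

#' Counts per million, optionally log2
#'
#' CPM uses the effective library size (raw library size times the RLE size
#' factor).  In log mode, a prior count (default 0.5, scaled per sample in
#' proportion to effective library size so the offset is the same on the
#' CPM scale) stabilises zeros:
#' \code{log2((y + pc_j) / (N_j + 2 pc_j) * 1e6)}.
#'
#' @param x An \code{fdx_counts} object.
#' @param factors Size factors from \code{\link{rle_size_factors}}, or
#'   \code{NULL} for unnormalised (raw library size) CPM.
#' @param log Return log2 CPM?
#' @param prior_count Average prior count added in log mode.
#' @return Numeric matrix, features x samples.
#' @export
cpm_matrix <- function(x, factors = NULL, log = FALSE, prior_count = 0.5) {
  stopifnot(inherits(x, "fdx_counts"))
  lib <- colSums(x$counts)
  if (any(lib <= 0)) stop("zero library size")
  eff <- eff_libsize(x, factors)
  if (!log) return(sweep(x$counts, 2L, eff, "/") * 1e6)
  pc <- prior_count * eff / mean(eff)
  shifted <- sweep(x$counts, 2L, pc, "+")
  sweep(log2(shifted), 2L, log2(eff + 2 * pc), "-") + log2(1e6)
}

#' Define a two-group contrast over the sample sheet
#'
#' A contrast selects two disjoint sample groups by matching sample-sheet
#' columns; the reported fold change is group B over group A
#' (\code{log2fc = log2(B/A)}), so A is the reference.
#'
#' @param name Contrast label.
#' @param a,b Named lists of required sample-sheet values, e.g.
#'   \code{list(genotype = "healthy", treatment = "ctrl_rnai",
#'   fraction = "whole_cell")}.
#' @return Object of class \code{fdx_contrast}.
#' @examples
#' # disease contrast in the whole-cell fraction: C9 vs healthy, untreated
#' disease_contrast("whole_cell")
#' @export
make_contrast <- function(name, a, b) {
  structure(list(name = name, a = a, b = b), class = "fdx_contrast")
}

#' @rdname make_contrast
#' @param fraction Fraction the contrast is evaluated in.
#' @export
disease_contrast <- function(fraction = "whole_cell") {
  make_contrast(paste0("c9_disease_", fraction),
                a = list(genotype = "healthy", treatment = "ctrl_rnai",
                         fraction = fraction),
                b = list(genotype = "c9", treatment = "ctrl_rnai",
                         fraction = fraction))
}

#' @rdname make_contrast
#' @param genotype Genotype within which the depletion effect is tested.
#' @export
treated_contrast <- function(genotype = "c9", fraction = "whole_cell") {
  make_contrast(paste0(genotype, "_treated_", fraction),
                a = list(genotype = genotype, treatment = "ctrl_rnai",
                         fraction = fraction),
                b = list(genotype = genotype, treatment = "srsf1_rnai",
                         fraction = fraction))
}

match_samples <- function(samples, pred) {
  keep <- rep(TRUE, nrow(samples))
  for (col in names(pred)) keep <- keep & samples[[col]] %in% pred[[col]]
  which(keep)
}

contrast_groups <- function(x, contrast) {
  stopifnot(inherits(contrast, "fdx_contrast"))
  ia <- match_samples(x$samples, contrast$a)
  ib <- match_samples(x$samples, contrast$b)
  if (length(intersect(ia, ib)) > 0)
    stop("contrast groups overlap in contrast '", contrast$name, "'")
  if (length(ia) < 2 || length(ib) < 2)
    stop("contrast '", contrast$name, "' requires >= 2 samples per group (got ",
         length(ia), " and ", length(ib), ")")
  list(a = ia, b = ib)
}

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)  # a group fitted at zero contributes no information
  if (phi < 1e-10) return(sum(stats::dpois(y, mu, log = TRUE)))
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        ifelse(y > 0, y * log(phi * mu / (1 + phi * mu)), 0) -
        r * log1p(phi * mu))
}

# Cox-Reid adjusted profile likelihood for one feature: the group-mean fit
# is profiled out and the adjustment -0.5 log det(X'WX) removes most of the
# downward bias of the plain MLE at small replicate numbers.
nb_apl <- function(phi, y, mu, group) {
  w <- mu / (1 + phi * mu)
  gsum <- pmax(vapply(split(w, group), sum, numeric(1)), 1e-10)
  nb_loglik(y, mu, phi) - 0.5 * sum(log(gsum))
}

# Per-group NB mean fit with offsets.  At phi = 0 this is the Poisson MLE
# (ratio of sums); for phi > 0 the score equation
# sum_j (y_j - q N_j) / (1 + phi q N_j) = 0 is solved by fixed-point
# iteration, which matters when library sizes differ within a group.
fit_group_means <- function(y, eff, group, phi = 0) {
  q <- vapply(split(seq_along(y), group),
              function(j) sum(y[j]) / sum(eff[j]), numeric(1))
  if (phi > 1e-10) {
    idx <- split(seq_along(y), group)
    for (k in seq_along(q)) {
      j <- idx[[k]]
      qk <- q[k]
      if (qk <= 0) next
      for (it in 1:8) {
        d <- 1 + phi * qk * eff[j]
        qnew <- sum(y[j] / d) / sum(eff[j] / d)
        if (abs(qnew - qk) < 1e-8 * (qk + 1e-8)) { qk <- qnew; break }
        qk <- qnew
      }
      q[k] <- qk
    }
  }
  q[as.character(group)] * eff
}

#' Estimate negative-binomial dispersions with empirical-Bayes shrinkage
#'
#' Per-feature (genewise) dispersions are estimated by maximising the
#' Cox-Reid adjusted profile likelihood of the NB model
#' (variance = mu + phi mu^2) with group means fitted through effective
#' library-size offsets.  A mean-dispersion trend is fitted by lowess on the
#' square-root scale, and genewise values are shrunk toward the trend by a
#' weighted combination on the log scale with weight
#' \code{prior_df / (prior_df + residual_df)}.
#'
#' @param x An \code{fdx_counts} object (already low-count filtered).
#' @param group Factor of group labels, one per sample (samples in groups of
#'   size 1 contribute no replication information).
#' @param factors RLE size factors; computed from \code{x} when \code{NULL}.
#' @param prior_df Prior degrees of freedom controlling shrinkage strength.
#' @return Object of class \code{fdx_dispersion}: data frame with columns
#'   \code{feature_id}, \code{ave_log2cpm}, \code{genewise}, \code{trend},
#'   \code{shrunk}, plus attributes \code{weight} and \code{factors}.
#' @export
estimate_dispersion <- function(x, group, factors = NULL, prior_df = 10) {
  stopifnot(inherits(x, "fdx_counts"))
  group <- droplevels(as.factor(group))
  if (length(group) != ncol(x$counts)) stop("group labels do not match samples")
  if (max(table(group)) < 2) stop("need >= 2 samples in some group")
  counts <- x$counts
  if (any(rowSums(counts) == 0))
    stop("feature(s) with all-zero counts; run filter_low_counts first")
  if (is.null(factors)) factors <- rle_size_factors(x)
  eff <- eff_libsize(x, factors)
  n_groups <- nlevels(group)
  resid_df <- ncol(counts) - n_groups
  if (resid_df < 1) stop("no residual degrees of freedom")

  genewise <- vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    obj <- function(lp) {
      ph <- exp(lp)
      nb_apl(ph, y, fit_group_means(y, eff, group, ph), group)
    }
    opt <- stats::optimize(obj, lower = log(1e-6), upper = log(30),
                           maximum = TRUE)
    phi <- exp(opt$maximum)
    # collapse to the Poisson boundary when it fits at least as well
    if (nb_apl(1e-8, y, fit_group_means(y, eff, group), group) >=
        opt$objective) phi <- 0
    phi
  }, numeric(1))

  ave <- rowMeans(cpm_matrix(x, factors, log = TRUE))
  lo <- stats::lowess(ave, sqrt(genewise), f = 0.5)
  trend <- pmax(stats::approx(lo$x, lo$y, xout = ave, rule = 2)$y, 0)^2

  w <- prior_df / (prior_df + resid_df)
  eps <- 1e-6
  shrunk <- exp((1 - w) * log(genewise + eps) + w * log(trend + eps)) - eps
  shrunk <- pmax(shrunk, 0)

  out <- data.frame(feature_id = rownames(counts), ave_log2cpm = ave,
                    genewise = genewise, trend = trend, shrunk = shrunk,
                    stringsAsFactors = FALSE)
  structure(out, class = c("fdx_dispersion", "data.frame"),
            weight = w, factors = factors, resid_df = resid_df)
}

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi < 1e-10) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
              (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

#' Negative-binomial quasi-likelihood differential-expression test
#'
#' For each feature, an NB generalized linear model with log link and
#' effective-library-size offsets is fitted under the full (two group means)
#' and null (one mean) models at the shrunk dispersion.  The quasi-dispersion
#' is estimated from the residual deviance, moderated across features by
#' empirical Bayes (\code{limma::squeezeVar}), and the contrast is tested
#' with a quasi-F statistic on (1, residual + prior) degrees of freedom.
#' A feature is flagged a DEG when \code{|log2fc| > log2(fc_threshold)} and
#' \code{p < p_threshold}; BH q-values are reported alongside but the DEG
#' rule uses the raw p-value.
#'
#' @param x Filtered \code{fdx_counts}.
#' @param contrast An \code{fdx_contrast}; fold change is group B over A.
#' @param dispersions \code{fdx_dispersion} computed on the same features.
#' @param fc_threshold Fold-change cut (on the natural scale; 2 means
#'   \code{|log2fc| > 1}).
#' @param p_threshold Raw p-value cut.
#' @param dispersion_type Which dispersion enters the GLM fit.  The default
#'   \code{"trend"} follows quasi-likelihood practice: the stable trended
#'   value is used in the fit and gene-specific variability is carried by
#'   the quasi-dispersion, which keeps the test calibrated at small
#'   replicate numbers.
#' @param ql Use the quasi-likelihood F-test (default).  With
#'   \code{ql = FALSE} a plain likelihood-ratio chi-square test at the
#'   given dispersion is performed instead, which reduces to the Poisson
#'   GLM deviance test when the dispersion is zero.
#' @return Data frame of class \code{fdx_de}: \code{feature_id},
#'   \code{log2fc}, \code{mean_log2cpm}, \code{p}, \code{q}, \code{is_deg};
#'   attribute \code{contrast} records the contrast name.
#' @export
de_test <- function(x, contrast, dispersions, fc_threshold = 2,
                    p_threshold = 0.05,
                    dispersion_type = c("trend", "shrunk", "genewise"),
                    ql = TRUE) {
  stopifnot(inherits(x, "fdx_counts"), inherits(dispersions, "fdx_dispersion"))
  dispersion_type <- match.arg(dispersion_type)
  if (!identical(dispersions$feature_id, rownames(x$counts)))
    stop("dispersion table does not match the count matrix features")
  grp <- contrast_groups(x, contrast)
  factors <- attr(dispersions, "factors")
  eff <- eff_libsize(x, factors)
  ja <- grp$a; jb <- grp$b
  jj <- c(ja, jb)
  gfac <- factor(rep(c("a", "b"), c(length(ja), length(jb))))
  n <- length(jj)
  df_resid <- n - 2L

  counts <- x$counts[, jj, drop = FALSE]
  effj <- eff[jj]
  phi <- dispersions[[dispersion_type]]

  sum_a <- rowSums(x$counts[, ja, drop = FALSE])
  sum_b <- rowSums(x$counts[, jb, drop = FALSE])
  Na <- sum(eff[ja]); Nb <- sum(eff[jb])
  # equal-weight mean of per-sample normalized abundances: exactly
  # invariant under a per-sample rescaling absorbed by the size factor
  cpm_all <- sweep(x$counts[, jj, drop = FALSE], 2L, effj, "/") * 1e6
  qa <- rowMeans(cpm_all[, seq_along(ja), drop = FALSE])
  qb <- rowMeans(cpm_all[, length(ja) + seq_along(jb), drop = FALSE])
  log2fc <- log2(qb + 0.5) - log2(qa + 0.5)
  mean_log2cpm <- log2((sum_a + sum_b + 0.5) / (Na + Nb) * 1e6)

  dev_full <- numeric(nrow(counts))
  dev_null <- numeric(nrow(counts))
  gnull <- factor(rep("all", n))
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    mu_full <- fit_group_means(y, effj, gfac, phi[g])
    mu_null <- fit_group_means(y, effj, gnull, phi[g])
    dev_full[g] <- nb_deviance(y, mu_full, phi[g])
    dev_null[g] <- nb_deviance(y, mu_null, phi[g])
  }

  if (ql) {
    s2 <- dev_full / df_resid
    sq <- limma::squeezeVar(pmax(s2, 1e-8), df = df_resid)
    df_total <- df_resid + sq$df.prior
    Fstat <- pmax(dev_null - dev_full, 0) / sq$var.post
    p <- stats::pf(Fstat, 1, df_total, lower.tail = FALSE)
  } else {
    p <- stats::pchisq(pmax(dev_null - dev_full, 0), df = 1,
                       lower.tail = FALSE)
  }

  q <- bh_adjust(p)
  is_deg <- abs(log2fc) > log2(fc_threshold) & p < p_threshold
  out <- data.frame(feature_id = rownames(x$counts), log2fc = log2fc,
                    mean_log2cpm = mean_log2cpm, p = p, q = q,
                    is_deg = is_deg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("fdx_de", "data.frame"), contrast = contrast$name,
            fc_threshold = fc_threshold, p_threshold = p_threshold)
}

#' One-way ANOVA differential expression for continuous expression matrices
#'
#' Per-feature one-way between-subject ANOVA across the supplied groups on a
#' log-scale expression matrix (e.g. RMA-normalised microarray values), with
#' the fold change taken between a designated pair of groups.  Features with
#' zero total variance are reported with p = 1 and log2fc = 0.
#'
#' @param exprs Numeric matrix, features x samples, log2 scale.
#' @param groups Group labels, one per sample; every group needs >= 2
#'   samples.
#' @param fc_pair Length-2 character: reference group then comparison group
#'   for the fold change (defaults to the first two group levels).
#' @param fc_threshold,p_threshold DEG selection thresholds.
#' @return Data frame of class \code{fdx_de} with the same columns as
#'   \code{\link{de_test}}.
#' @export
anova_de <- function(exprs, groups, fc_pair = NULL, fc_threshold = 2,
                     p_threshold = 0.05) {
  exprs <- as.matrix(exprs)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(exprs)) stop("group labels do not match samples")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (is.null(fc_pair)) fc_pair <- levels(groups)[1:2]
  if (!all(fc_pair %in% levels(groups))) stop("fc_pair not among group levels")

  n <- ncol(exprs)
  k <- nlevels(groups)
  gm <- vapply(levels(groups),
               function(g) rowMeans(exprs[, groups == g, drop = FALSE]),
               numeric(nrow(exprs)))
  if (is.null(dim(gm)))
    gm <- matrix(gm, nrow = 1, dimnames = list(NULL, levels(groups)))
  grand <- rowMeans(exprs)
  ss_between <- as.numeric(gm^2 %*% as.numeric(sizes)) - n * grand^2
  ss_total <- rowSums(exprs^2) - n * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  ss_between <- pmax(ss_between, 0)

  df1 <- k - 1
  df2 <- n - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  degenerate <- ss_total < 1e-12
  p[degenerate | is.nan(p)] <- 1
  log2fc <- gm[, fc_pair[2L]] - gm[, fc_pair[1L]]
  log2fc[degenerate] <- 0

  q <- bh_adjust(p)
  is_deg <- abs(log2fc) > log2(fc_threshold) & p < p_threshold
  out <- data.frame(feature_id = rownames(exprs) %||% as.character(seq_len(nrow(exprs))),
                    log2fc = log2fc, mean_log2cpm = grand, p = p, q = q,
                    is_deg = is_deg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("fdx_de", "data.frame"),
            contrast = paste(fc_pair, collapse = "_vs_"),
            fc_threshold = fc_threshold, p_threshold = p_threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with input validation; a thin
#' validated wrapper around \code{stats::p.adjust}.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Roll transcript-level DE calls up to genes
#'
#' Optional "any significant isoform" aggregation: a gene is flagged when at
#' least one of its features is a DEG.  This is an interpretation layer, not
#' part of the core feature-level analysis.
#'
#' @param de An \code{fdx_de} table.
#' @param gene_of Named character vector mapping feature ids to gene ids.
#' @return Data frame with \code{gene_id}, \code{n_features}, \code{n_deg},
#'   \code{is_deg}.
#' @export
rollup_genes <- function(de, gene_of) {
  gid <- unname(gene_of[de$feature_id])
  if (anyNA(gid)) stop("feature(s) without a gene assignment")
  agg <- stats::aggregate(de$is_deg, by = list(gene_id = gid),
                          FUN = function(v) c(length(v), sum(v)))
  data.frame(gene_id = agg$gene_id,
             n_features = agg$x[, 1L], n_deg = agg$x[, 2L],
             is_deg = agg$x[, 2L] > 0, stringsAsFactors = FALSE)
}
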