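#' Simplified differential exon-usage test
#'
#' For every exon of a multi-exon gene, the exon's counts are compared with
#' the summed counts of the gene's other exons between two sample groups via
#' a 2x2 chi-square association test on pooled counts.  Biological
#' replication is accounted for by a design-effect (Rao-Scott style)
#' correction: the within-group replicate heterogeneity chi-square divided
#' by its degrees of freedom estimates an overdispersion factor, and the
#' pooled statistic is deflated by it (floored at 1) before the p-value is
#' taken from a 1-df chi-square.  BH adjustment is applied across all tested
#' exons and significance is called at \code{q < fdr}.
#'
#' Single-exon genes are excluded (counted, not an error); an exon whose
#' gene has zero counts in either group is skipped.
#'
#' @param exons An \code{fdx_exons} object.
#' @param group Two-level factor over the samples (columns).
#' @param fdr BH false-discovery-rate threshold.
#' @return Data frame of class \code{fdx_exon_usage}: \code{exon_id},
#'   \code{gene_id}, \code{pi_a}, \code{pi_b} (pooled usage proportions per
#'   group), \code{stat}, \code{p}, \code{q}, \code{significant}.
#'   Attributes \code{n_excluded_single_exon} and \code{n_skipped_zero}
#'   keep the bookkeeping: tested + excluded + skipped = input exons.
#' @export
exon_usage_test <- function(exons, group, fdr = 0.05) {
  stopifnot(inherits(exons, "fdx_exons"))
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (length(group) != ncol(exons$counts))
    stop("group labels do not match samples")
  counts <- exons$counts
  gene <- exons$exons$gene_id

  exons_per_gene <- table(gene)
  single <- names(exons_per_gene)[exons_per_gene < 2]
  excl <- gene %in% single
  n_excluded <- sum(excl)
  if (n_excluded > 0)
    message(n_excluded, " exon(s) of single-exon genes excluded")

  ja <- which(group == levels(group)[1L])
  jb <- which(group == levels(group)[2L])
  gene_tot <- rowsum(counts, gene)               # genes x samples
  other <- gene_tot[gene, , drop = FALSE] - counts

  res <- vector("list", nrow(counts))
  skipped <- logical(nrow(counts))
  for (e in which(!excl)) {
    ga <- sum(counts[e, ja]) + sum(other[e, ja])
    gb <- sum(counts[e, jb]) + sum(other[e, jb])
    if (ga == 0 || gb == 0) { skipped[e] <- TRUE; next }
    xa <- sum(counts[e, ja]); xb <- sum(counts[e, jb])
    oa <- ga - xa; ob <- gb - xb
    pi_a <- xa / ga; pi_b <- xb / gb
    p_pool <- (xa + xb) / (ga + gb)
    if (p_pool <= 0 || p_pool >= 1) {
      stat <- 0; p <- 1
    } else {
      # pooled 2x2 chi-square, no continuity correction
      stat <- (xa - ga * p_pool)^2 / (ga * p_pool * (1 - p_pool)) +
        (xb - gb * p_pool)^2 / (gb * p_pool * (1 - p_pool))
      # replicate-level heterogeneity within groups -> design effect
      het <- 0; df_het <- 0
      for (jj in list(ja, jb)) {
        nj <- counts[e, jj] + other[e, jj]
        use <- nj > 0
        if (sum(use) > 1) {
          pg <- sum(counts[e, jj]) / sum(nj)
          if (pg > 0 && pg < 1) {
            het <- het + sum((counts[e, jj][use] - nj[use] * pg)^2 /
                               (nj[use] * pg * (1 - pg)))
            df_het <- df_het + sum(use) - 1
          }
        }
      }
      infl <- if (df_het > 0) max(1, het / df_het) else 1
      stat <- stat / infl
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
    res[[e]] <- data.frame(exon_id = rownames(counts)[e], gene_id = gene[e],
                           pi_a = pi_a, pi_b = pi_b, stat = stat, p = p,
                           stringsAsFactors = FALSE)
  }
  n_skipped <- sum(skipped)
  tested <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(tested)) {
    tested <- data.frame(exon_id = character(0), gene_id = character(0),
                         pi_a = numeric(0), pi_b = numeric(0),
                         stat = numeric(0), p = numeric(0))
  }
  tested$q <- if (nrow(tested) > 0) bh_adjust(tested$p) else numeric(0)
  tested$significant <- tested$q < fdr
  rownames(tested) <- NULL
  structure(tested, class = c("fdx_exon_usage", "data.frame"),
            n_excluded_single_exon = n_excluded, n_skipped_zero = n_skipped,
            group_levels = levels(group), fdr = fdr)
}

#' Roll exon-usage calls up to genes
#'
#' A gene is called splicing-altered when it has at least one significant
#' exon.  This rollup is an interpretation layer over the exon-level test.
#'
#' @param usage An \code{fdx_exon_usage} table.
#' @return Data frame with \code{gene_id}, \code{n_exons_tested},
#'   \code{n_significant}, \code{altered}.
#' @export
exon_usage_genes <- function(usage) {
  agg <- stats::aggregate(usage$significant,
                          by = list(gene_id = usage$gene_id),
                          FUN = function(v) c(length(v), sum(v)))
  data.frame(gene_id = agg$gene_id, n_exons_tested = agg$x[, 1L],
             n_significant = agg$x[, 2L], altered = agg$x[, 2L] > 0,
             stringsAsFactors = FALSE)
}
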