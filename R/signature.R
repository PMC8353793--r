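#' Build the disease-modifying expression signature
#'
#' Intersects the DEG sets of a disease contrast and a treatment contrast
#' and classifies each shared feature as \code{reversed} (opposite fold
#' change signs: the treatment reverts the disease direction) or
#' \code{concordant}.  A descriptive restoration metric
#' \code{|log2fc_disease + log2fc_treated|} is reported (small values mean
#' near-complete reversal) but plays no part in the classification.
#'
#' @param disease,treated \code{fdx_de} tables sharing a feature id space.
#' @return Data frame of class \code{fdx_signature}: \code{feature_id},
#'   \code{log2fc_disease}, \code{log2fc_treated}, \code{status},
#'   \code{restoration}; rows sorted reversed-first, then by
#'   \code{|log2fc_disease|} descending, ties by feature id.
#' @export
build_signature <- function(disease, treated) {
  stopifnot(is.data.frame(disease), is.data.frame(treated),
            "is_deg" %in% names(disease), "is_deg" %in% names(treated))
  ids <- intersect(disease$feature_id[disease$is_deg],
                   treated$feature_id[treated$is_deg])
  ld <- disease$log2fc[match(ids, disease$feature_id)]
  lt <- treated$log2fc[match(ids, treated$feature_id)]
  if (any(ld == 0 | lt == 0))
    stop("DEG with log2fc exactly 0; upstream tables are inconsistent")
  status <- ifelse(sign(ld) == -sign(lt), "reversed", "concordant")
  out <- data.frame(feature_id = ids, log2fc_disease = ld,
                    log2fc_treated = lt, status = status,
                    restoration = abs(ld + lt), stringsAsFactors = FALSE)
  ord <- order(match(out$status, c("reversed", "concordant")),
               -abs(out$log2fc_disease), out$feature_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fdx_signature", "data.frame"))
}

#' Decompose two or three id sets into disjoint Venn regions
#'
#' @param sets Named list of 2 or 3 vectors of ids.
#' @return Named integer vector of exclusive region sizes.  For two sets
#'   \code{A}, \code{B}: \code{A_only}, \code{B_only}, \code{A_B}.  For
#'   three, all seven exclusive regions.  Regions are disjoint and sum to
#'   the size of the union.
#' @export
venn_decompose <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    stop("venn_decompose takes 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "_"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "_")), use.names = FALSE)
  out <- vapply(combos, function(cb) sum(key == cb), integer(1))
  names(out)[seq_along(sets)] <- paste0(names(sets), "_only")
  out
}

#' Ordered fold-change matrix for a signature
#'
#' Two-column matrix of the disease and treatment log2 fold changes, the
#' form used for signature heatmaps.  With \code{cluster = TRUE} rows are
#' ordered by average-linkage hierarchical clustering on the Euclidean
#' distance of the signed fold-change pairs; ties are resolved by input
#' order (the ordering \code{stats::hclust} returns is deterministic for a
#' fixed input order).
#'
#' @param entries An \code{fdx_signature} table (non-empty).
#' @param cluster Reorder rows by clustering?
#' @return Numeric matrix with columns \code{log2fc_disease},
#'   \code{log2fc_treated}, rownames the feature ids.
#' @export
signature_matrix <- function(entries, cluster = TRUE) {
  if (!is.data.frame(entries) || nrow(entries) == 0)
    stop("empty signature: nothing to order")
  m <- cbind(log2fc_disease = entries$log2fc_disease,
             log2fc_treated = entries$log2fc_treated)
  rownames(m) <- entries$feature_id
  if (cluster && nrow(m) > 1) {
    hc <- stats::hclust(stats::dist(m), method = "average")
    m <- m[hc$order, , drop = FALSE]
  }
  m
}
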