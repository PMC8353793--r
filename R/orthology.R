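#' Restrict a homology table to pairs whose source gene is in a set
#'
#' One-to-many homology is preserved: a gene with several homologues yields
#' several pairs.
#'
#' @param deg_ids Character vector of gene ids on the source side.
#' @param table Homology data frame with columns \code{gene_a},
#'   \code{gene_b}.
#' @param side \code{"a_to_b"} (source is \code{gene_a}) or \code{"b_to_a"}.
#' @return The subset of \code{table} whose source-side gene is in
#'   \code{deg_ids}.
#' @export
map_orthologs <- function(deg_ids, table, side = c("a_to_b", "b_to_a")) {
  side <- match.arg(side)
  src <- if (side == "a_to_b") table$gene_a else table$gene_b
  out <- table[src %in% deg_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species direction concordance of expression changes
#'
#' For every homology pair with both genes present in their species' DE
#' table, classifies the pair as \code{similar} (fold-change signs agree)
#' or \code{opposite}.  The strict tally counts pairs where both sides are
#' DEGs; a lenient view over one-sided pairs (exactly one side a DEG, the
#' other side's direction taken from its sub-threshold fold change) is
#' returned alongside, since published tallies sometimes include genes with
#' at least one differentially-expressed change.
#'
#' @param de_a,de_b \code{fdx_de} tables for species A and B (matched
#'   contrasts).
#' @param table Homology data frame (\code{gene_a}, \code{gene_b}).
#' @return List of class \code{fdx_concordance}: \code{records} (both-DEG
#'   pairs with directions and class), \code{n_similar}, \code{n_opposite},
#'   \code{one_sided} (lenient records), \code{n_one_sided_similar},
#'   \code{n_one_sided_opposite}, \code{n_skipped} (pairs with a gene
#'   missing from its table).
#' @export
direction_concordance <- function(de_a, de_b, table) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(table)))
  ia <- match(table$gene_a, de_a$feature_id)
  ib <- match(table$gene_b, de_b$feature_id)
  present <- !is.na(ia) & !is.na(ib)
  n_skipped <- sum(!present)
  if (n_skipped > 0)
    message(n_skipped, " homology pair(s) skipped: gene absent from a DE table")
  tab <- table[present, , drop = FALSE]
  ia <- ia[present]; ib <- ib[present]
  la <- de_a$log2fc[ia]; lb <- de_b$log2fc[ib]
  da <- de_a$is_deg[ia]; db <- de_b$is_deg[ib]

  mk <- function(idx) {
    if (length(idx) == 0)
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        direction_a = character(0), direction_b = character(0),
                        class = character(0), stringsAsFactors = FALSE))
    data.frame(gene_a = tab$gene_a[idx], gene_b = tab$gene_b[idx],
               direction_a = ifelse(la[idx] > 0, "up", "down"),
               direction_b = ifelse(lb[idx] > 0, "up", "down"),
               class = ifelse(sign(la[idx]) == sign(lb[idx]),
                              "similar", "opposite"),
               stringsAsFactors = FALSE)
  }
  records <- mk(which(da & db))
  one_sided <- mk(which(xor(da, db)))
  structure(list(records = records,
                 n_similar = sum(records$class == "similar"),
                 n_opposite = sum(records$class == "opposite"),
                 one_sided = one_sided,
                 n_one_sided_similar = sum(one_sided$class == "similar"),
                 n_one_sided_opposite = sum(one_sided$class == "opposite"),
                 n_skipped = n_skipped),
            class = "fdx_concordance")
}

#' @export
print.fdx_concordance <- function(x, ...) {
  cat(sprintf("ortholog concordance: %d similar, %d opposite (both-DEG pairs);",
              x$n_similar, x$n_opposite),
      sprintf("%d one-sided pairs (%d similar, %d opposite by raw sign)\n",
              nrow(x$one_sided), x$n_one_sided_similar,
              x$n_one_sided_opposite))
  invisible(x)
}

#' Fully conserved reciprocal ortholog pairs across two signatures
#'
#' A homology pair is fully conserved when both genes belong to their
#' species' disease-modifying signature, the disease directions match
#' across species, the treated directions match across species, and within
#' each species the treatment reverses the disease direction (both entries
#' have \code{status == "reversed"}).
#'
#' @param sig_a,sig_b \code{fdx_signature} tables from
#'   \code{\link{build_signature}}.
#' @param table Homology data frame (\code{gene_a}, \code{gene_b}).
#' @return Data frame: \code{gene_a}, \code{gene_b},
#'   \code{disease_dir_a}, \code{disease_dir_b}, \code{treated_dir_a},
#'   \code{treated_dir_b}, \code{fully_conserved}.
#' @export
reciprocal_pairs <- function(sig_a, sig_b, table) {
  ia <- match(table$gene_a, sig_a$feature_id)
  ib <- match(table$gene_b, sig_b$feature_id)
  keep <- !is.na(ia) & !is.na(ib)
  tab <- table[keep, , drop = FALSE]
  ia <- ia[keep]; ib <- ib[keep]
  dir <- function(v) ifelse(v > 0, "up", "down")
  da <- sig_a$log2fc_disease[ia]; db <- sig_b$log2fc_disease[ib]
  ta <- sig_a$log2fc_treated[ia]; tb <- sig_b$log2fc_treated[ib]
  fully <- sign(da) == sign(db) & sign(ta) == sign(tb) &
    sign(da) == -sign(ta) & sign(db) == -sign(tb)
  out <- data.frame(gene_a = tab$gene_a, gene_b = tab$gene_b,
                    disease_dir_a = dir(da), disease_dir_b = dir(db),
                    treated_dir_a = dir(ta), treated_dir_b = dir(tb),
                    fully_conserved = fully, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
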