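#' Classify nuclear-export-altered transcripts
#'
#' Applies the fold-change intersection rule: a transcript is called
#' export-stimulated when its cytoplasmic fold change exceeds
#' \code{cyt_threshold} while its whole-cell level is stable
#' (\code{|log2fc_wct| < log2(wct_threshold)}), export-inhibited for the
#' mirror-image condition, and \code{none} otherwise.  The defaults (both 3)
#' implement screening for transcripts with altered cytoplasmic abundance
#' (FC > 3) but unchanged steady-state whole-cell levels (FC < 3).  No
#' p-value condition is applied by default; \code{require_cyt_p} adds
#' \code{p < 0.05} on the cytoplasmic side.
#'
#' Features present in only one compartment's results (e.g. filtered out in
#' the other) are unclassifiable, not stable: they are returned separately
#' with a reason.
#'
#' @param wct_results,cyt_results \code{fdx_de} tables for the same
#'   biological contrast evaluated in the whole-cell and cytoplasmic
#'   fractions.
#' @param cyt_threshold Cytoplasmic fold-change cut (natural scale).
#' @param wct_threshold Whole-cell stability band (natural scale).
#' @param require_cyt_p Additionally require cytoplasmic p < 0.05.
#' @return Data frame of class \code{fdx_export}: \code{feature_id},
#'   \code{log2fc_wct}, \code{log2fc_cyt}, \code{call} (one of
#'   \code{export_inhibited}, \code{export_stimulated}, \code{none});
#'   attribute \code{unclassifiable} is a data frame of feature_id/reason.
#' @export
classify_export <- function(wct_results, cyt_results, cyt_threshold = 3,
                            wct_threshold = 3, require_cyt_p = FALSE) {
  ca <- attr(wct_results, "contrast"); cb <- attr(cyt_results, "contrast")
  if (!is.null(ca) && !is.null(cb)) {
    strip <- function(s) sub("_(whole_cell|cytoplasmic|wct|cyt)$", "", s)
    if (strip(ca) != strip(cb))
      stop("contrast mismatch between compartments: '", ca, "' vs '", cb, "'")
  }
  shared <- intersect(wct_results$feature_id, cyt_results$feature_id)
  if (length(shared) == 0) stop("no features shared between the two tables")
  only_w <- setdiff(wct_results$feature_id, shared)
  only_c <- setdiff(cyt_results$feature_id, shared)
  unclassifiable <- data.frame(
    feature_id = c(only_w, only_c),
    reason = c(rep("absent_from_cyt", length(only_w)),
               rep("absent_from_wct", length(only_c))),
    stringsAsFactors = FALSE)

  iw <- match(shared, wct_results$feature_id)
  ic <- match(shared, cyt_results$feature_id)
  lw <- wct_results$log2fc[iw]
  lc <- cyt_results$log2fc[ic]
  stable_wct <- abs(lw) < log2(wct_threshold)
  ok_p <- if (require_cyt_p) cyt_results$p[ic] < 0.05 else TRUE
  call <- rep("none", length(shared))
  call[stable_wct & ok_p & lc > log2(cyt_threshold)] <- "export_stimulated"
  call[stable_wct & ok_p & lc < -log2(cyt_threshold)] <- "export_inhibited"

  out <- data.frame(feature_id = shared, log2fc_wct = lw, log2fc_cyt = lc,
                    call = call, stringsAsFactors = FALSE)
  structure(out, class = c("fdx_export", "data.frame"),
            unclassifiable = unclassifiable,
            cyt_threshold = cyt_threshold, wct_threshold = wct_threshold)
}

#' Tally export calls by direction
#'
#' @param calls An \code{fdx_export} table.
#' @return Named integer vector \code{(n_inhibited, n_stimulated, n_none)};
#'   the three counts partition the classifiable features.
#' @export
export_direction_summary <- function(calls) {
  stopifnot(is.data.frame(calls), "call" %in% names(calls))
  c(n_inhibited = sum(calls$call == "export_inhibited"),
    n_stimulated = sum(calls$call == "export_stimulated"),
    n_none = sum(calls$call == "none"))
}
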