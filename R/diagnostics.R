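#' Transcriptome coverage by the Lander-Waterman relation
#'
#' Coverage = read length x number of reads / size of the sequenced target.
#' For paired-end data each read pair contributes twice the read length,
#' and for transcriptome sequencing the target is the transcribed fraction
#' of the genome.  For example, 104 million 2x150 bp read pairs against a
#' 3 Gb genome of which 10 percent is transcribed give
#' (2 x 150 x 104e6) / (3e9 x 0.10) = 104-fold coverage.
#'
#' @param read_length Read length in bp.
#' @param n_reads Number of reads (read pairs when \code{paired}).
#' @param paired Paired-end sequencing?
#' @param genome_size Genome size in bp.
#' @param transcribed_fraction Fraction of the genome transcribed, in
#'   (0, 1].
#' @return Fold coverage (numeric scalar).
#' @export
lander_waterman_coverage <- function(read_length, n_reads, paired = FALSE,
                                     genome_size, transcribed_fraction = 1) {
  if (read_length <= 0 || n_reads <= 0 || genome_size <= 0)
    stop("read_length, n_reads and genome_size must be positive")
  if (transcribed_fraction <= 0 || transcribed_fraction > 1)
    stop("transcribed_fraction must lie in (0, 1]")
  mult <- if (paired) 2 else 1
  (mult * read_length * n_reads) / (genome_size * transcribed_fraction)
}

#' Classical multidimensional scaling of samples
#'
#' Embeds samples by classical (metric) MDS of the pairwise Euclidean
#' distances computed on the most variable features of a log-CPM matrix.
#' Axes are canonicalized by flipping each axis so that its
#' largest-magnitude coordinate is positive, making the output
#' deterministic and invariant to feature order.
#'
#' @param logcpm Numeric matrix, features x samples (log2 CPM).
#' @param top_n Number of most-variable features used (all if fewer).
#' @param dims Number of embedding dimensions.
#' @return Numeric matrix, samples x dims, rownames the sample ids.
#' @export
sample_mds <- function(logcpm, top_n = 500, dims = 2) {
  logcpm <- as.matrix(logcpm)
  n <- ncol(logcpm)
  if (n < dims + 1) stop("need at least dims + 1 samples")
  v <- apply(logcpm, 1L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(logcpm)))]
  d <- stats::dist(t(logcpm[keep, , drop = FALSE]))
  coords <- stats::cmdscale(d, k = dims)
  if (ncol(coords) < dims) {  # degenerate geometry: pad zero axes
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- colnames(logcpm)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

#' Marker-set expression summaries
#'
#' Mean log-CPM of each marker set (e.g. neuron, astrocyte and
#' oligodendrocyte markers) per sample group, with the fraction of marker
#' ids actually present in the matrix.  Sets with no present marker are
#' reported with \code{NA} summaries rather than raising an error.
#'
#' @param x An \code{fdx_counts} object.
#' @param markers Named list of character vectors of feature ids.
#' @param factors RLE size factors (computed when \code{NULL}).
#' @param group Grouping labels over samples; default one group per sample.
#' @return Data frame: \code{set}, \code{group}, \code{mean_log2cpm},
#'   \code{n_present}, \code{n_total}, \code{coverage}.
#' @export
marker_summary <- function(x, markers, factors = NULL, group = NULL) {
  stopifnot(inherits(x, "fdx_counts"), is.list(markers))
  if (any(lengths(markers) == 0)) stop("marker sets must be non-empty")
  if (is.null(names(markers))) names(markers) <- paste0("set", seq_along(markers))
  if (is.null(factors)) factors <- rle_size_factors(x)
  if (is.null(group)) group <- x$samples$sample_id
  group <- as.factor(group)
  lc <- cpm_matrix(x, factors, log = TRUE)
  out <- list()
  for (nm in names(markers)) {
    present <- intersect(markers[[nm]], rownames(lc))
    for (g in levels(group)) {
      m <- if (length(present) > 0) {
        mean(lc[present, group == g, drop = FALSE])
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        set = nm, group = g, mean_log2cpm = m,
        n_present = length(present), n_total = length(markers[[nm]]),
        coverage = length(present) / length(markers[[nm]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
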