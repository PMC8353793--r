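GENOTYPE_LEVELS  <- c("healthy", "c9")
TREATMENT_LEVELS <- c("ctrl_rnai", "srsf1_rnai")
FRACTION_LEVELS  <- c("whole_cell", "cytoplasmic", "nuclear")

#' Construct a count matrix object
#'
#' Bundles an integer feature-by-sample count matrix with its sample
#' metadata.  This is the container every downstream stage consumes.
#'
#' @param counts Non-negative integer matrix, features in rows (rownames are
#'   feature ids) and samples in columns (colnames are sample ids).
#' @param samples Data frame with one row per column of \code{counts} and
#'   columns \code{sample_id}, \code{genotype} (\code{healthy}/\code{c9}),
#'   \code{treatment} (\code{ctrl_rnai}/\code{srsf1_rnai}), \code{fraction}
#'   (\code{whole_cell}/\code{cytoplasmic}/\code{nuclear}),
#'   \code{individual_id} and \code{replicate}.
#' @return An object of class \code{fdx_counts}: a list with elements
#'   \code{counts} and \code{samples}, columns ordered as in \code{samples}.
#' @export
fdx_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyNA(counts)) stop("counts contain missing values")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature ids: ", rownames(counts)[duplicated(rownames(counts))][1L])
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  samples <- validate_sample_sheet(samples)
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_meta) > 0)
    stop("no sample metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  absent <- setdiff(samples$sample_id, colnames(counts))
  if (length(absent) > 0)
    stop("sample sheet lists sample(s) absent from the count matrix: ",
         paste(absent, collapse = ", "))
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "fdx_counts")
}

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "treatment", "fraction", "individual_id",
           "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(samples[[col]])), levels)
    if (length(bad) > 0)
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  }
  chk("genotype", GENOTYPE_LEVELS)
  chk("treatment", TREATMENT_LEVELS)
  chk("fraction", FRACTION_LEVELS)
  if (any(samples$replicate != round(samples$replicate) | samples$replicate < 1))
    stop("replicate must be a positive integer")
  samples
}

#' @export
print.fdx_counts <- function(x, ...) {
  cat(sprintf("fdx_counts: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("fractions: ", paste(names(table(x$samples$fraction)),
                           table(x$samples$fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fdx_counts <- function(x) dim(x$counts)

#' Subset a count matrix object by feature and/or sample
#'
#' @param x An \code{fdx_counts} object.
#' @param i Feature index (ids, logical, or positions).
#' @param j Sample index.
#' @param ... Unused.
#' @return An \code{fdx_counts} restricted to the selected rows/columns.
#' @export
`[.fdx_counts` <- function(x, i, j, ...) {
  counts <- x$counts
  samples <- x$samples
  if (!missing(i)) counts <- counts[i, , drop = FALSE]
  if (!missing(j)) {
    counts <- counts[, j, drop = FALSE]
    samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(counts = counts, samples = samples), class = "fdx_counts")
}

#' Read a count matrix with its sample sheet
#'
#' Accepts either a dense TSV (first column feature ids, header row sample
#' ids) or a MatrixMarket triplet file accompanied by sidecar
#' \code{features.tsv} / \code{samples.tsv} id files in the same directory.
#' Sample columns are reordered to follow the sample sheet.
#'
#' @param path Path to the count TSV or \code{.mtx} file.
#' @param sample_sheet_path Path to the sample-sheet TSV (columns
#'   \code{sample_id}, \code{genotype}, \code{treatment}, \code{fraction},
#'   \code{individual_id}, \code{replicate}).
#' @return An \code{fdx_counts} object.
#' @export
read_count_matrix <- function(path, sample_sheet_path) {
  samples <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE,
                               comment.char = "#")
  if (grepl("\\.mtx$", path)) {
    counts <- read_mtx_triplet(path)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1L]])
  }
  fdx_counts(counts, samples)
}

# Minimal MatrixMarket coordinate reader with features.tsv/samples.tsv
# sidecars; kept dependency-free because the files are plain triplets.
read_mtx_triplet <- function(path) {
  dirn <- dirname(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^%", lines)]
  hdr <- scan(text = lines[1L], quiet = TRUE)
  trip <- if (length(lines) > 1L) {
    matrix(scan(text = lines[-1L], quiet = TRUE), ncol = 3L, byrow = TRUE)
  } else matrix(numeric(0), ncol = 3L)
  m <- matrix(0, nrow = hdr[1L], ncol = hdr[2L])
  if (nrow(trip) > 0) m[trip[, 1:2, drop = FALSE]] <- trip[, 3L]
  rownames(m) <- readLines(file.path(dirn, "features.tsv"))
  colnames(m) <- readLines(file.path(dirn, "samples.tsv"))
  m
}

#' Write a count matrix and sample sheet as TSV
#'
#' Inverse of \code{\link{read_count_matrix}}: the written files round-trip
#' counts and metadata exactly.
#'
#' @param x An \code{fdx_counts} object.
#' @param path Output path for the count TSV.
#' @param sample_sheet_path Output path for the sample-sheet TSV (omit to
#'   skip writing the sheet).
#' @return Invisibly, \code{path}.
#' @export
write_count_matrix <- function(x, path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "fdx_counts"))
  tab <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(x$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with an audit header
#'
#' Writes any result data frame with a stable column order, floats at full
#' precision (>= 10 significant digits), and a comment line recording the
#' package version and, when supplied, the random seed of the run, so output
#' files are self-describing.
#'
#' @param table Data frame (may have zero rows).
#' @param path Output path.
#' @param seed Optional integer seed recorded in the header comment.
#' @return Invisibly, \code{path}.
#' @export
write_results_table <- function(table, path, seed = NULL) {
  table <- as.data.frame(table)
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("fracdex"))
  hdr <- sprintf("# fracdex %s", ver)
  if (!is.null(seed)) hdr <- paste0(hdr, sprintf(" seed=%d", as.integer(seed)))
  writeLines(hdr, con)
  num <- vapply(table, is.double, logical(1))
  table[num] <- lapply(table[num], function(v) sprintf("%.12g", v))
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{write_results_table}
#'
#' @param path Path to the TSV.
#' @return Data frame; the audit comment line is skipped.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a two-column cross-species homology table
#'
#' @param path TSV whose first two columns are gene ids in species A and B.
#'   One-to-many and many-to-many pairs are allowed; duplicate pairs are
#'   dropped.
#' @return Data frame with columns \code{gene_a}, \code{gene_b}.
#' @export
read_homology_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("homology table needs two columns")
  out <- data.frame(gene_a = as.character(tab[[1L]]),
                    gene_b = as.character(tab[[2L]]),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read an exon count table
#'
#' @param path TSV with columns \code{exon_id}, \code{gene_id}, then one
#'   column per sample.
#' @return A list with \code{exons} (data frame of exon_id/gene_id) and
#'   \code{counts} (matrix, rownames exon ids), class \code{fdx_exons}.
#' @export
read_exon_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("exon_id", "gene_id") %in% names(tab)))
  counts <- as.matrix(tab[, setdiff(names(tab), c("exon_id", "gene_id")),
                          drop = FALSE])
  rownames(counts) <- tab$exon_id
  fdx_exons(tab$exon_id, tab$gene_id, counts)
}

#' Construct an exon count object
#'
#' @param exon_id Character vector of unique exon ids.
#' @param gene_id Character vector assigning each exon to one gene.
#' @param counts Non-negative integer matrix, exons x samples.
#' @return Object of class \code{fdx_exons}.
#' @export
fdx_exons <- function(exon_id, gene_id, counts) {
  if (anyDuplicated(exon_id)) stop("duplicated exon ids")
  if (length(exon_id) != nrow(counts)) stop("exon ids / counts mismatch")
  if (any(counts < 0) || anyNA(counts)) stop("invalid exon counts")
  storage.mode(counts) <- "double"
  rownames(counts) <- exon_id
  structure(list(exons = data.frame(exon_id = as.character(exon_id),
                                    gene_id = as.character(gene_id),
                                    stringsAsFactors = FALSE),
                 counts = counts),
            class = "fdx_exons")
}

#' Write an exon count object as TSV
#'
#' @param x An \code{fdx_exons} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_exon_counts <- function(x, path) {
  tab <- data.frame(exon_id = x$exons$exon_id, gene_id = x$exons$gene_id,
                    x$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{sim_config}} arguments.
#' @return A \code{sim_config} object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}
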