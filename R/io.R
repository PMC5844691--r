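#' Read and write tab-delimited probe-by-sample matrices
#'
#' Matrix files are UTF-8 TSV: first column the probe identifier, header row
#' the sample identifiers, decimal point (never comma). Readers never
#' reorder rows or columns. Duplicate probe or sample identifiers and
#' non-numeric cells are errors (reported with their coordinates).
#'
#' @param path File path.
#' @return `read_matrix_tsv()`: a numeric matrix with probe row names and
#'   sample column names.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  probes <- tab[[1L]]
  if (anyDuplicated(probes))
    stop_fmt("duplicate probe identifier in %s: %s", path,
             probes[duplicated(probes)][1L])
  samples <- names(tab)[-1L]
  if (anyDuplicated(samples))
    stop_fmt("duplicate sample identifier in %s: %s", path,
             samples[duplicated(samples)][1L])
  vals <- as.matrix(tab[-1L])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num) && !all(is.na(vals) == is.na(num))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop_fmt("non-numeric cell in %s at probe '%s', sample '%s'",
             path, probes[bad[1L]], samples[bad[2L]])
  }
  dimnames(num) <- list(probes, samples)
  num
}

#' @rdname read_matrix_tsv
#' @param x Numeric matrix with row and column names.
#' @param id_column Header for the first (probe-identifier) column.
#' @export
write_matrix_tsv <- function(x, path, id_column = "probe_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample-design tables
#'
#' The design is a TSV with columns `sample_id`, `subset`, `donor` (extra
#' columns pass through). It carries the paired-donor structure used by the
#' paired differential tests.
#'
#' @param path File path.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "subset", "donor")
  if (!all(need %in% names(d)))
    stop_fmt("design file %s must have columns: %s", path,
             paste(need, collapse = ", "))
  d
}

#' @rdname read_design_tsv
#' @param design Data frame with at least `sample_id`, `subset`, `donor`.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Cp (quantification-cycle) table
#'
#' CSV with one row per well: `sample_id, donor, subset, gene, cp` for
#' expression qPCR, or `region, antibody, cp` (plus free metadata columns)
#' for ChIP-qPCR. Cp values must be finite and positive.
#'
#' @param path CSV file path.
#' @export
read_cp_csv <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cp" %in% names(d)) stop_fmt("Cp table %s must have a 'cp' column", path)
  if (any(!is.finite(d$cp)) || any(d$cp <= 0))
    stop_fmt("Cp values must be finite and > 0 in %s", path)
  d
}

#' @rdname read_cp_csv
#' @param table Data frame with a `cp` column.
#' @export
write_cp_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
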