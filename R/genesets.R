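#' Gene sets and ranked lists
#'
#' `gene_set()` builds a named collection of gene symbols (the unit GSEA
#' operates on); `ranked_list()` builds a score-ordered identifier list.
#' Ranked lists are always stored in descending score order with ties broken
#' by identifier (radix/C ordering), so results do not depend on input order
#' or locale.
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene symbols; duplicates are collapsed
#'   keeping first occurrence order.
#' @param description Free-text description (GMT column 2).
#' @return `gene_set()`: an object of class `gene_set` with fields `name`,
#'   `description`, `genes`.
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_fmt("gene set name must be a non-empty string")
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, "-", length(x$genes), "genes\n")
  invisible(x)
}

#' @rdname gene_set
#' @param ids Identifiers (unique).
#' @param scores Numeric scores, same length as `ids`.
#' @return `ranked_list()`: a data.frame of class `ranked_list` with columns
#'   `id` and `score`, ordered by descending score.
#' @export
ranked_list <- function(ids, scores) {
  ids <- as.character(ids)
  scores <- as.numeric(scores)
  if (length(ids) != length(scores))
    stop_fmt("ids and scores must have equal length")
  if (anyDuplicated(ids))
    stop_fmt("ranked list identifiers must be unique (duplicate: %s)",
             ids[duplicated(ids)][1L])
  if (any(!is.finite(scores)))
    stop_fmt("ranked list scores must be finite")
  o <- order_desc_ties_by_id(scores, ids)
  structure(data.frame(id = ids[o], score = scores[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list>", nrow(x), "identifiers, scores in [",
      round(min(x$score), 4), ",", round(max(x$score), 4), "]\n")
  invisible(x)
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-delimited Broad format: one set per line, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed on read; empty gene fields are dropped.
#'
#' @param path File path.
#' @return `read_gmt()`: a list of [gene_set] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_fmt("malformed GMT line %d in %s: expected >= 3 tab-separated fields, got %d",
               i, path, length(f))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    out[[i]] <- gene_set(f[[1L]], genes, description = f[[2L]])
  }
  out
}

#' @rdname read_gmt
#' @param genesets List of [gene_set] objects.
#' @export
write_gmt <- function(genesets, path) {
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  lines <- vapply(genesets, function(gs) {
    paste(c(gs$name, if (nzchar(gs$description)) gs$description else gs$name,
            gs$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write RNK ranked-list files
#'
#' RNK is the two-column tab-delimited format `identifier<TAB>score` with no
#' header. On read the list is re-ordered to descending score with ties
#' broken by identifier, the package-wide deterministic tie rule.
#'
#' @param path File path.
#' @return `read_rnk()`: a [ranked_list].
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "character"),
                           col.names = c("id", "score"), quote = "")
  scores <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(scores))
    stop_fmt("non-numeric score at line %d of %s", which(is.na(scores))[1L],
             path)
  ranked_list(tab$id, scores)
}

#' @rdname read_rnk
#' @param ranked A [ranked_list].
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  utils::write.table(
    data.frame(ranked$id, format(ranked$score, digits = 15, trim = TRUE,
                                 scientific = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
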