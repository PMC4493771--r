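#' Construct a count matrix of unambiguous tag counts
#'
#' The raw input of the pipeline: one row per gene, one column per library,
#' holding the number of unambiguously assigned clean tags, together with
#' the gene length used for RPKM normalisation.
#'
#' @param counts Integer matrix (genes x libraries) with column names; all
#'   entries non-negative integers.
#' @param gene_id Character vector of unique gene identifiers (one per row).
#' @param length_bp Positive integer gene lengths in base pairs.
#' @param libraries Required library labels. Defaults to the seven-library
#'   design \code{DTA_LIBRARIES}; pass \code{NULL} to accept the matrix's
#'   own column set (library mode).
#' @return An object of class \code{count_matrix}: list with elements
#'   \code{gene_id}, \code{length_bp} and \code{counts}.
#' @export
count_matrix <- function(counts, gene_id, length_bp,
                         libraries = DTA_LIBRARIES) {
  counts <- as.matrix(counts)
  if (length(gene_id) != nrow(counts) || length(length_bp) != nrow(counts))
    stopf("gene_id and length_bp must have one entry per count row")
  if (anyDuplicated(gene_id))
    stopf("duplicate gene ids: %s",
          paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!is.numeric(counts) || any(is.na(counts)))
    stopf("counts must be numeric with no missing values")
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  if (any(is.na(length_bp)) || any(length_bp < 1) ||
      any(length_bp != floor(length_bp)))
    stopf("gene lengths must be integers >= 1")
  if (is.null(colnames(counts)))
    stopf("count matrix must carry library labels as column names")
  if (!is.null(libraries)) {
    missing <- setdiff(libraries, colnames(counts))
    if (length(missing))
      stopf("missing required library column(s): %s",
            paste(missing, collapse = ", "))
    counts <- counts[, libraries, drop = FALSE]
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_id
  structure(list(gene_id = as.character(gene_id),
                 length_bp = as.integer(length_bp),
                 counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries (%s)\n",
              length(x$gene_id), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a tag count table from TSV
#'
#' Expected layout: columns \code{gene_id}, \code{length_bp}, then one
#' integer column per library. Duplicate gene ids, negative or
#' non-integer counts are rejected with the offending line reported.
#'
#' @param path Path to a tab-separated file.
#' @inheritParams count_matrix
#' @return A \code{count_matrix}.
#' @export
load_counts <- function(path, libraries = DTA_LIBRARIES) {
  df <- tryCatch(read_tsv(path, colClasses = "character"),
                 error = function(e) stopf("malformed TSV '%s': %s",
                                           path, conditionMessage(e)))
  req <- c("gene_id", "length_bp")
  if (!all(req %in% names(df)))
    stopf("'%s': required column(s) missing: %s", path,
          paste(setdiff(req, names(df)), collapse = ", "))
  libcols <- setdiff(names(df), req)
  num <- suppressWarnings(
    vapply(df[libcols], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, libcols))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    r <- bad[1, 1]; c <- libcols[bad[1, 2]]
    stopf("'%s' line %d: column '%s' value '%s' is not a non-negative integer",
          path, r + 1L, c, df[[c]][r])
  }
  len <- suppressWarnings(as.numeric(df$length_bp))
  if (any(is.na(len)))
    stopf("'%s' line %d: length_bp is not numeric", path,
          which(is.na(len))[1] + 1L)
  count_matrix(num, df$gene_id, len, libraries = libraries)
}

#' Write a count matrix as TSV
#'
#' @param x A \code{count_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = x$gene_id, length_bp = x$length_bp,
                   x$counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Library sequencing and mapping bookkeeping
#'
#' Computes the mapped and unique-match percentages from per-library read
#' accounting integers, in the presentation of the standard sequencing
#' statistics table (percentages rounded half-up to two decimals).
#'
#' @param raw Data frame with columns \code{library}, \code{total_reads},
#'   \code{mapped_reads}, \code{unique_match_reads} (non-negative integers
#'   with \code{unique <= mapped <= total}).
#' @return Data frame of class \code{library_stats} with added
#'   \code{mapped_pct} and \code{unique_pct} columns.
#' @export
library_stats <- function(raw) {
  req <- c("library", "total_reads", "mapped_reads", "unique_match_reads")
  if (!all(req %in% names(raw)))
    stopf("library_stats input needs columns: %s", paste(req, collapse = ", "))
  with(raw, {
    if (any(total_reads == 0)) stopf("total_reads = 0: rates undefined")
    if (any(mapped_reads > total_reads) ||
        any(unique_match_reads > mapped_reads) ||
        any(c(total_reads, mapped_reads, unique_match_reads) < 0))
      stopf("read accounting must satisfy 0 <= unique <= mapped <= total")
  })
  out <- raw[req]
  out$mapped_pct <- pct(raw$mapped_reads, raw$total_reads)
  out$unique_pct <- pct(raw$unique_match_reads, raw$total_reads)
  class(out) <- c("library_stats", "data.frame")
  out
}

#' RPKM normalisation of a count matrix
#'
#' RPKM (reads per kilobase of transcript per million assigned reads) for
#' gene g in library l is \code{1e9 * C_gl / (N_l * L_g)}, where N_l is the
#' library's total gene-assigned unambiguous count and L_g the gene length
#' in bp.
#'
#' @param counts A \code{count_matrix}.
#' @return An object of class \code{expression_matrix}: list with
#'   \code{rpkm} (numeric matrix) and \code{denominators} (per-library N).
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- colSums(counts$counts)
  if (any(N == 0))
    stopf("library with zero assigned reads: %s",
          paste(names(N)[N == 0], collapse = ", "))
  rpkm <- 1e9 * sweep(counts$counts, 2, N, "/") / counts$length_bp
  structure(list(rpkm = rpkm, denominators = N,
                 gene_id = counts$gene_id, length_bp = counts$length_bp),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d libraries (RPKM)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

#' Write an RPKM matrix as TSV
#'
#' @param x An \code{expression_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rpkm <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_id, x$rpkm, check.names = FALSE)
  write_tsv(df, path)
}
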