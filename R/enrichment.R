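#' Read a two-column term-to-gene annotation table
#'
#' @param path TSV with columns \code{term_id}, \code{gene_id}; the
#'   vocabulary ("GO-like" or "KEGG-like") may be recorded in a
#'   \code{# vocabulary: ...} comment on the first line.
#' @return Data frame (term_id, gene_id) with a \code{vocabulary}
#'   attribute.
#' @export
load_annotation <- function(path) {
  first <- readLines(path, n = 1)
  vocab <- if (grepl("^#\\s*vocabulary:", first))
    sub("^#\\s*vocabulary:\\s*", "", first) else NA_character_
  df <- read_tsv(path, comment.char = "#")
  if (!all(c("term_id", "gene_id") %in% names(df)))
    stopf("'%s': annotation table needs columns term_id, gene_id", path)
  attr(df, "vocabulary") <- vocab
  df
}

#' Write an annotation map as TSV
#'
#' @param annot Data frame (term_id, gene_id), optionally carrying a
#'   \code{vocabulary} attribute written as a header comment.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vocab <- attr(annot, "vocabulary")
  if (!is.null(vocab) && !is.na(vocab))
    writeLines(sprintf("# vocabulary: %s", vocab), con)
  utils::write.table(annot[c("term_id", "gene_id")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Storey q-values with a fixed-lambda null-proportion estimate
#'
#' \code{pi0 = min(1, mean(p > lambda) / (1 - lambda))}; q-values are the
#' Benjamini-Hochberg step-up values scaled by \code{pi0}.
#'
#' @param pvalues P-values in [0, 1].
#' @param lambda Tuning point for the pi0 estimate (default 0.5).
#' @return Q-values in input order.
#' @export
storey_qvalue <- function(pvalues, lambda = 0.5) {
  if (any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  pi0 <- min(1, mean(pvalues > lambda) / (1 - lambda))
  pmin(1, pi0 * stats::p.adjust(pvalues, method = "BH"))
}

#' Term over-representation by the upper-tail hypergeometric test
#'
#' For each term with K background members of which k are in the study
#' set (n study genes from an N-gene background),
#' \code{p = P(X >= k | N, K, n)}. P-values are adjusted across the
#' vocabulary's terms and results sorted by p.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   \code{background}).
#' @param background Character vector: the gene universe.
#' @param annot Annotation data frame (term_id, gene_id); genes outside
#'   the background are dropped with a warning.
#' @param adjust "BH" (default; reported as FDR) or "storey" (Q-value).
#' @param threshold Significance cutoff on the adjusted value
#'   (default 0.05).
#' @return Data frame of class \code{enrichment_result} with columns
#'   \code{term_id, k, K, n, N, pvalue, adjusted, significant}, sorted by
#'   \code{pvalue}.
#' @export
hypergeom_enrich <- function(study, background, annot,
                             adjust = c("BH", "storey"), threshold = 0.05) {
  adjust <- match.arg(adjust)
  study <- unique(study); background <- unique(background)
  if (length(study) == 0 || length(background) == 0)
    stopf("study and background sets must be non-empty")
  if (!all(study %in% background))
    stopf("study set must be a subset of the background universe")
  outside <- !(annot$gene_id %in% background)
  if (any(outside)) {
    warning(sprintf(
      "%d annotation entr%s outside the background universe dropped",
      sum(outside), if (sum(outside) == 1) "y" else "ies"))
    annot <- annot[!outside, , drop = FALSE]
  }
  terms <- split(unique(annot[c("term_id", "gene_id")])$gene_id,
                 unique(annot[c("term_id", "gene_id")])$term_id)
  N <- length(background); n <- length(study)
  K <- vapply(terms, length, 0L)
  k <- vapply(terms, function(g) sum(g %in% study), 0L)
  pv <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  adj <- switch(adjust, BH = bh_fdr(pv), storey = storey_qvalue(pv))
  out <- data.frame(term_id = names(terms), k = k, K = K, n = n, N = N,
                    pvalue = pv, adjusted = adj,
                    significant = adj <= threshold, row.names = NULL)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "vocabulary") <- attr(annot, "vocabulary")
  attr(out, "adjust") <- adjust
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Screen responsive genes into the candidate set
#'
#' A responsive gene is a candidate iff it belongs to at least one
#' significant GO-like term or at least one significant KEGG-like pathway;
#' the two branches are unioned and deduplicated.
#'
#' @param go_results,kegg_results \code{enrichment_result}s for the two
#'   vocabularies.
#' @param annot_go,annot_kegg The annotation tables the results were
#'   computed from.
#' @param responsive Character vector of responsive gene ids (or a
#'   \code{responsive_set}, whose union is used).
#' @return List of class \code{candidate_set}: \code{candidates} (sorted
#'   character vector), \code{go_branch}, \code{kegg_branch}, and
#'   \code{sizes} (named: go, kegg, intersection, union).
#' @export
select_candidates <- function(go_results, kegg_results, annot_go,
                              annot_kegg, responsive) {
  if (inherits(responsive, "responsive_set"))
    responsive <- responsive$union$gene_id
  branch <- function(res, annot) {
    sig <- res$term_id[res$significant]
    sort(unique(intersect(
      annot$gene_id[annot$term_id %in% sig], responsive)))
  }
  go_branch <- branch(go_results, annot_go)
  kegg_branch <- branch(kegg_results, annot_kegg)
  cand <- sort(union(go_branch, kegg_branch))
  structure(list(
    candidates = cand, go_branch = go_branch, kegg_branch = kegg_branch,
    sizes = c(go = length(go_branch), kegg = length(kegg_branch),
              intersection = length(intersect(go_branch, kegg_branch)),
              union = length(cand))),
    class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "candidate_set: GO branch %d, KEGG branch %d, union %d\n",
    x$sizes["go"], x$sizes["kegg"], x$sizes["union"]))
  invisible(x)
}
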