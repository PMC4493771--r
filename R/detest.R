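#' Audic-Claverie exact test for two unreplicated count libraries
#'
#' Tests whether a gene's tag count differs between two libraries of sizes
#' N1 and N2. Conditional on observing \code{x} tags in library 1, the
#' count \code{y} in library 2 follows
#' \deqn{p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^{x+y+1}),}
#' a negative binomial with size \code{x + 1} and success probability
#' \code{N1/(N1+N2)}. The two-sided p-value doubles the smaller conditional
#' tail (both tails include the observed count) and caps at 1. Tails are
#' evaluated through the negative-binomial distribution function, which is
#' numerically stable for counts up to at least 1e6.
#'
#' The statistic is nearly, but not exactly, symmetric in the two library
#' roles: swapping \code{(x, N1)} with \code{(y, N2)} changes the
#' conditioning variable, so the two orientations can disagree by up to a
#' factor of about two deep in the tails.
#'
#' @param x,y Non-negative integer counts in the reference and test
#'   library (vectorised).
#' @param n1,n2 Library sizes (total assigned counts), each >= 1.
#' @return Two-sided p-values in [0, 1].
#' @references Audic S, Claverie JM (1997). The significance of digital
#'   gene expression profiles. Genome Research 7:986-995.
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stopf("counts must be non-negative integers")
  if (any(n1 < 1) || any(n2 < 1))
    stopf("library sizes must be >= 1")
  p <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = p)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = p, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotone enforcement; output order
#' matches input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values in [0, 1], same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' One Audic-Claverie test per gene, FDR adjustment across all genes of the
#' comparison, and the dual gate of the tag-profiling design: a gene is
#' called up/down iff \code{fdr <= fdr_threshold} AND its fold change is at
#' least \code{fc_threshold} in either direction. Fold change is computed
#' on pseudo-counted library-size-normalised counts,
#' \code{log2(((y + a)/N2) / ((x + a)/N1))} with \code{a = 1}, so on/off
#' genes keep a finite value. Genes exactly at either threshold are
#' included (the gates are inclusive).
#'
#' @param counts A \code{count_matrix}.
#' @param pair Length-2 character vector \code{c(reference, test)} of
#'   library labels present in \code{counts}.
#' @param fdr_threshold FDR gate (default 0.001).
#' @param fc_threshold Fold-change gate on the linear scale (default 4).
#' @param pseudocount Pseudo-count added to both libraries' counts for the
#'   fold-change estimate (default 1).
#' @return Data frame of class \code{deg_table} with columns
#'   \code{gene_id, x, y, log2fc, pvalue, fdr, direction}; attributes
#'   \code{pair}, \code{denominators}.
#' @export
call_degs <- function(counts, pair, fdr_threshold = 0.001,
                      fc_threshold = 4, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(counts$gene_id) == 0) stopf("empty gene universe")
  if (length(pair) != 2 || pair[1] == pair[2])
    stopf("pair must be two distinct library labels")
  if (!all(pair %in% colnames(counts$counts)))
    stopf("pair labels not in count matrix: %s",
          paste(setdiff(pair, colnames(counts$counts)), collapse = ", "))
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stopf("fdr_threshold must be in (0, 1]")
  if (fc_threshold < 1) stopf("fc_threshold must be >= 1")
  N <- colSums(counts$counts)
  x <- counts$counts[, pair[1]]
  y <- counts$counts[, pair[2]]
  n1 <- N[[pair[1]]]; n2 <- N[[pair[2]]]
  pv <- ac_pvalue(x, y, n1, n2)
  fdr <- bh_fdr(pv)
  lfc <- log2(((y + pseudocount) / n2) / ((x + pseudocount) / n1))
  called <- fdr <= fdr_threshold & abs(lfc) >= log2(fc_threshold)
  direction <- ifelse(called, ifelse(lfc > 0, "up", "down"), "none")
  out <- data.frame(gene_id = counts$gene_id, x = x, y = y,
                    log2fc = lfc, pvalue = pv, fdr = fdr,
                    direction = direction, row.names = NULL)
  attr(out, "pair") <- pair
  attr(out, "denominators") <- c(n1, n2)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Run the six fixed comparisons of the seven-library design
#'
#' @inheritParams call_degs
#' @param pairs List of comparisons as returned by \code{\link{dta_pairs}}.
#' @return Named list of \code{deg_table}s.
#' @export
call_all_degs <- function(counts, pairs = dta_pairs(),
                          fdr_threshold = 0.001, fc_threshold = 4) {
  lapply(pairs, function(p)
    call_degs(counts, p, fdr_threshold = fdr_threshold,
              fc_threshold = fc_threshold))
}
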