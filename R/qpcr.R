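#' Read a qPCR Ct table from TSV
#'
#' @param path TSV with columns \code{gene_id, sample, replicate, ct,
#'   is_reference}.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  req <- c("gene_id", "sample", "replicate", "ct", "is_reference")
  if (!all(req %in% names(df)))
    stopf("'%s': Ct table needs columns %s", path, paste(req, collapse = ", "))
  df$is_reference <- as.logical(df$is_reference)
  if (any(df$ct <= 0)) stopf("Ct values must be positive")
  df
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each target gene and sample, \code{dCt = mean target Ct - mean of
#' the reference genes' per-gene mean Cts}; \code{ddCt = dCt(sample) -
#' dCt(calibrator)}; \code{RE = 2^(-ddCt)}. Replicates are averaged on
#' the Ct scale. Two reference genes per sample are expected (their Cts
#' are combined by arithmetic mean, i.e. geometric mean of their linear
#' expressions); the calibrator sample (pre-treatment, 0 d) has RE = 1 by
#' construction.
#'
#' @param records Ct data frame (columns \code{gene_id, sample,
#'   replicate, ct, is_reference}).
#' @param calibrator Sample label used as the RE = 1 baseline
#'   (default "0d").
#' @return Data frame of class \code{relative_expression}: columns
#'   \code{gene_id, sample, re}.
#' @export
delta_delta_ct <- function(records, calibrator = "0d") {
  if (!calibrator %in% records$sample)
    stopf("calibrator sample '%s' absent from the Ct table", calibrator)
  samples <- unique(records$sample)
  refs <- records[records$is_reference, , drop = FALSE]
  ref_by_sample <- lapply(stats::setNames(samples, samples), function(s) {
    r <- refs[refs$sample == s, , drop = FALSE]
    if (length(unique(r$gene_id)) < 2)
      stopf("sample '%s' lacks the two reference genes", s)
    mean(vapply(split(r$ct, r$gene_id), mean, 0))
  })
  targets <- records[!records$is_reference, , drop = FALSE]
  out <- do.call(rbind, lapply(split(targets, targets$gene_id), function(g) {
    ct_mean <- vapply(split(g$ct, g$sample), mean, 0)
    have <- names(ct_mean)
    if (!calibrator %in% have)
      stopf("gene '%s' has no calibrator measurement", g$gene_id[1])
    dct <- ct_mean - unlist(ref_by_sample[have])
    ddct <- dct - dct[[calibrator]]
    data.frame(gene_id = g$gene_id[1], sample = have, re = 2^(-ddct),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Concordance of qPCR and DTA expression profiles
#'
#' Operationalises the cross-validation of tag-profiling calls by qPCR: by
#' default a gene is concordant iff the direction of its day-1 change
#' relative to pre-treatment agrees between the qPCR relative expression
#' (day-1 sample vs the calibrator, which is 1) and the DTA RPKM profile
#' (ETH1 vs CK0). A change needs at least \code{min_fold} in either
#' direction to count as a direction; two no-changes agree. The
#' alternative metric is the Spearman correlation of the full four-point
#' profiles (0d/1d/2d/3d vs CK0/ETH1/ETH2/ETH3), concordant iff rho > 0.
#'
#' @param qpcr A \code{relative_expression} table with samples "0d",
#'   "1d", "2d", "3d".
#' @param dta An \code{expression_matrix} over the seven-library design.
#' @param genes Genes to compare (default: all genes in \code{qpcr}).
#' @param min_fold Minimal fold change to call a direction (default 1.5).
#' @param metric "direction" (default) or "spearman".
#' @param rpkm_pseudo Pseudo-RPKM added to both sides of the DTA ratio so
#'   zero-RPKM genes stay finite (default 0.1).
#' @return List of class \code{concordance_summary}: \code{per_gene}
#'   (data frame gene_id, concordant), \code{n_concordant},
#'   \code{n_total}, \code{pct_concordant}.
#' @export
concordance <- function(qpcr, dta, genes = unique(qpcr$gene_id),
                        min_fold = 1.5, metric = c("direction", "spearman"),
                        rpkm_pseudo = 0.1) {
  metric <- match.arg(metric)
  stopifnot(inherits(dta, "expression_matrix"))
  absent <- setdiff(genes, rownames(dta$rpkm))
  if (length(absent) == 0)
    absent <- setdiff(genes, unique(qpcr$gene_id))
  if (length(absent))
    stopf("gene(s) absent from one side: %s",
          paste(utils::head(absent, 5), collapse = ", "))
  dir_of <- function(fold) {
    ifelse(fold >= min_fold, 1L, ifelse(fold <= 1 / min_fold, -1L, 0L))
  }
  conc <- vapply(genes, function(g) {
    q <- qpcr[qpcr$gene_id == g, ]
    r <- dta$rpkm[g, ]
    if (metric == "direction") {
      q1 <- q$re[q$sample == "1d"]
      if (length(q1) != 1) stopf("gene '%s' lacks a day-1 qPCR value", g)
      dfold <- (r[["ETH1"]] + rpkm_pseudo) / (r[["CK0"]] + rpkm_pseudo)
      dir_of(q1) == dir_of(dfold)
    } else {
      qe <- q$re[match(c("0d", "1d", "2d", "3d"), q$sample)]
      de <- r[c("CK0", "ETH1", "ETH2", "ETH3")]
      rho <- suppressWarnings(
        stats::cor(qe, de, method = "spearman"))
      !is.na(rho) && rho > 0
    }
  }, logical(1))
  structure(list(
    per_gene = data.frame(gene_id = genes, concordant = unname(conc),
                          row.names = NULL),
    n_concordant = sum(conc), n_total = length(conc),
    pct_concordant = pct(sum(conc), length(conc))),
    class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance: %d / %d genes (%.2f%%)\n",
              x$n_concordant, x$n_total, x$pct_concordant))
  invisible(x)
}
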