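#' Configuration of an end-to-end pipeline run
#'
#' Exactly one of \code{counts_path} (with annotation paths) or \code{sim}
#' (a \code{\link{sim_config}}) must be supplied.
#'
#' @param counts_path Path to a count TSV in the documented layout.
#' @param go_path,kegg_path Paths to the two annotation TSVs.
#' @param ct_path Optional qPCR Ct table TSV.
#' @param library_stats_path Optional TSV of per-library read accounting
#'   (library, total_reads, mapped_reads, unique_match_reads); when
#'   absent, the assigned-count totals stand in for all three columns.
#' @param sim A \code{sim_config} for a fully synthetic run (a Ct table
#'   is generated alongside when \code{sim_qpcr}).
#' @param sim_qpcr Generate and score a synthetic Ct table in simulate
#'   mode (default TRUE).
#' @param fdr_deg,fc DEG gates (defaults 0.001 and 4).
#' @param go_fdr,kegg_q Enrichment significance cutoffs (defaults 0.05).
#' @param kegg_adjust "BH" (default) or "storey" for the KEGG Q-value.
#' @param direction_aware Direction-aware background subtraction
#'   (default FALSE).
#' @param subcluster_method,subcluster_k Passed to
#'   \code{\link{subcluster}}.
#' @param concordance_metric Passed to \code{\link{concordance}}.
#' @param outdir Output directory (created if absent).
#' @param seed Seed for the synthetic stages.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(counts_path = NULL, go_path = NULL,
                            kegg_path = NULL, ct_path = NULL,
                            library_stats_path = NULL,
                            sim = NULL, sim_qpcr = TRUE,
                            fdr_deg = 0.001, fc = 4,
                            go_fdr = 0.05, kegg_q = 0.05,
                            kegg_adjust = "BH",
                            direction_aware = FALSE,
                            subcluster_method = "pattern",
                            subcluster_k = 2,
                            concordance_metric = "direction",
                            outdir = tempfile("dta_run_"), seed = 1) {
  if (is.null(sim) == is.null(counts_path))
    stopf("supply exactly one of counts_path or sim")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (fdr_deg <= 0 || fdr_deg > 1 || go_fdr <= 0 || go_fdr > 1 ||
      kegg_q <= 0 || kegg_q > 1)
    stopf("significance thresholds must lie in (0, 1]")
  if (fc < 1) stopf("fold-change threshold must be >= 1")
  structure(list(counts_path = counts_path, go_path = go_path,
                 kegg_path = kegg_path, ct_path = ct_path,
                 library_stats_path = library_stats_path,
                 sim = sim, sim_qpcr = sim_qpcr,
                 fdr_deg = fdr_deg, fc = fc, go_fdr = go_fdr,
                 kegg_q = kegg_q, kegg_adjust = kegg_adjust,
                 direction_aware = direction_aware,
                 subcluster_method = subcluster_method,
                 subcluster_k = subcluster_k,
                 concordance_metric = concordance_metric,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full tag-profiling pipeline
#'
#' Simulate or load counts; compute library bookkeeping and RPKM; run the
#' six Audic-Claverie comparisons; subtract control background and union
#' into the responsive set; run GO/KEGG enrichment and screen candidates;
#' classify candidates into temporal groups and sub-clusters; score qPCR
#' concordance when a Ct table is available. Every stage's table is
#' materialised under \code{config$outdir} so stages can be audited or
#' re-run in isolation, and the consolidated report is written as
#' \code{report.json}.
#'
#' @param config A \code{pipeline_config}.
#' @param quiet Suppress stage logging (default FALSE).
#' @return List of class \code{run_report}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  say <- function(...) if (!quiet) message(sprintf(...))
  truth <- NULL; ct <- NULL

  if (!is.null(config$sim)) {
    say("simulate: %d genes, depth %g, seed %d", config$sim$n_genes,
        config$sim$library_depth, config$sim$seed)
    ex <- generate_experiment(config$sim)
    counts <- ex$counts; truth <- ex$truth
    annot_go <- generate_annotation(config$sim, truth, "GO-like")
    annot_kegg <- generate_annotation(config$sim, truth, "KEGG-like")
    write_counts(counts, out("counts.tsv"))
    write_truth(truth, out("truth.json"))
    write_annotation(annot_go, out("annotation_go.tsv"))
    write_annotation(annot_kegg, out("annotation_kegg.tsv"))
    if (config$sim_qpcr &&
        sum(truth$pattern != "null") >= 1) {
      ct <- generate_ct_table(
        truth, n_target_genes = min(41, sum(truth$pattern != "null")),
        seed = config$sim$seed)
      write_tsv(ct, out("ct_table.tsv"))
    }
  } else {
    counts <- load_counts(config$counts_path)
    annot_go <- if (!is.null(config$go_path))
      load_annotation(config$go_path) else NULL
    annot_kegg <- if (!is.null(config$kegg_path))
      load_annotation(config$kegg_path) else NULL
    if (!is.null(config$ct_path)) ct <- read_ct_table(config$ct_path)
  }

  raw <- if (!is.null(config$library_stats_path)) {
    read_tsv(config$library_stats_path)
  } else {
    N <- colSums(counts$counts)
    data.frame(library = names(N), total_reads = N, mapped_reads = N,
               unique_match_reads = N, row.names = NULL)
  }
  stats <- library_stats(raw)
  write_tsv(stats, out("library_stats.tsv"))
  expr <- compute_rpkm(counts)
  write_rpkm(expr, out("rpkm.tsv"))
  say("quantify: %d genes, denominators %s", nrow(expr$rpkm),
      paste(fmt_int(expr$denominators), collapse = ", "))

  degs <- call_all_degs(counts, fdr_threshold = config$fdr_deg,
                        fc_threshold = config$fc)
  for (nm in names(degs)) write_tsv(degs[[nm]], out(paste0("degs_", nm, ".tsv")))
  deg_counts <- vapply(degs, function(d) sum(d$direction != "none"), 0L)
  say("detest: DEG counts %s",
      paste(names(deg_counts), deg_counts, sep = "=", collapse = ", "))

  resp <- build_responsive(degs, direction_aware = config$direction_aware)
  write_responsive(resp, out("responsive_union.tsv"))
  for (t in 1:3)
    write_tsv(resp$per_timepoint[[t]], out(sprintf("eth%d_ck%d.tsv", t, t)))
  eth_ck_sizes <- vapply(resp$per_timepoint, nrow, 0L)
  say("responsive: |ETHt/CKt| = %s; union = %d",
      paste(eth_ck_sizes, collapse = ", "), nrow(resp$union))

  background <- counts$gene_id[rowSums(counts$counts) > 0]
  study <- intersect(resp$union$gene_id, background)
  cand <- NULL; go_res <- NULL; kegg_res <- NULL
  if (!is.null(annot_go) && !is.null(annot_kegg) && length(study) > 0) {
    go_res <- hypergeom_enrich(study, background, annot_go,
                               adjust = "BH", threshold = config$go_fdr)
    kegg_res <- hypergeom_enrich(study, background, annot_kegg,
                                 adjust = config$kegg_adjust,
                                 threshold = config$kegg_q)
    write_tsv(go_res, out("enrichment_go.tsv"))
    write_tsv(kegg_res, out("enrichment_kegg.tsv"))
    cand <- select_candidates(go_res, kegg_res, annot_go, annot_kegg, resp)
    writeLines(cand$candidates, out("candidates.txt"))
    say("enrichment: GO branch %d, KEGG branch %d, candidates %d",
        cand$sizes["go"], cand$sizes["kegg"], cand$sizes["union"])
  }

  classification <- NULL; summary <- NULL
  if (!is.null(cand) && length(cand$candidates) > 0) {
    prof <- sign_profiles(resp, cand, degs)
    asg <- assign_group(prof)
    asg <- subcluster(asg, prof, method = config$subcluster_method,
                      k = config$subcluster_k)
    summary <- summarize_classification(asg, prof)
    write_classification(asg, summary, out("classification.tsv"),
                         out("heatmap_log2fc.tsv"))
    classification <- asg
    say("kinetics: groups %s",
        paste(names(summary$group_counts), summary$group_counts,
              sep = "=", collapse = ", "))
  }

  conc <- NULL
  if (!is.null(ct)) {
    re <- delta_delta_ct(ct, calibrator = "0d")
    write_tsv(re, out("relative_expression.tsv"))
    conc <- concordance(re, expr, metric = config$concordance_metric)
    jsonlite::write_json(
      list(n_concordant = conc$n_concordant, n_total = conc$n_total,
           pct_concordant = conc$pct_concordant),
      out("concordance.json"), auto_unbox = TRUE, digits = NA)
    say("qpcr: %d/%d concordant (%.2f%%)", conc$n_concordant,
        conc$n_total, conc$pct_concordant)
  }

  report <- structure(list(
    library_stats = stats,
    deg_counts = deg_counts,
    eth_ck_sizes = stats::setNames(as.integer(eth_ck_sizes),
                                   c("1d", "2d", "3d")),
    n_responsive = nrow(resp$union),
    branch_sizes = if (!is.null(cand)) cand$sizes else NULL,
    n_candidates = if (!is.null(cand)) length(cand$candidates) else 0L,
    classification = if (!is.null(summary))
      summary[c("n_total", "group_counts", "onset_up", "onset_down",
                "n_up", "n_down", "pct_up", "pct_down", "group_pct",
                "pct_day1")] else NULL,
    concordance = if (!is.null(conc))
      list(n_concordant = conc$n_concordant, n_total = conc$n_total,
           pct_concordant = conc$pct_concordant) else NULL,
    provenance = list(
      thresholds = list(fdr_deg = config$fdr_deg, fc = config$fc,
                        go_fdr = config$go_fdr, kegg_q = config$kegg_q),
      direction_aware = config$direction_aware,
      subcluster_method = config$subcluster_method,
      seed = config$seed,
      version = as.character(utils::packageVersion("dtakit")))),
    class = "run_report")
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Render a run report as human-readable text
#'
#' Formats the consolidated accounting with the conventions of the
#' sequencing bookkeeping tables: thousands separators on read counts,
#' two-decimal percentages.
#'
#' @param report A \code{run_report}.
#' @return Character vector of lines, invisibly printed.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  ls <- report$library_stats
  lines <- c(
    "Library sequencing and mapping",
    sprintf("  %-6s %15s %15s (%s) %15s (%s)", ls$library,
            fmt_int(ls$total_reads), fmt_int(ls$mapped_reads),
            fmt_pct(ls$mapped_pct), fmt_int(ls$unique_match_reads),
            fmt_pct(ls$unique_pct)),
    sprintf("  total clean reads: %s", fmt_int(sum(ls$total_reads))),
    "Differential expression",
    sprintf("  %s: %s DEGs", names(report$deg_counts),
            fmt_int(report$deg_counts)),
    sprintf("  ETHt/CKt sizes: %s; responsive union: %s",
            paste(fmt_int(report$eth_ck_sizes), collapse = ", "),
            fmt_int(report$n_responsive)))
  if (!is.null(report$branch_sizes))
    lines <- c(lines, sprintf(
      "  GO branch %s, KEGG branch %s, candidates %s",
      fmt_int(report$branch_sizes[["go"]]),
      fmt_int(report$branch_sizes[["kegg"]]),
      fmt_int(report$branch_sizes[["union"]])))
  cl <- report$classification
  if (!is.null(cl)) {
    lines <- c(lines, "Temporal classification",
      sprintf("  Group %-3s %s (%s)", names(cl$group_counts),
              fmt_int(cl$group_counts), fmt_pct(cl$group_pct)),
      sprintf("  day-1 responders: %s", fmt_pct(cl$pct_day1)),
      sprintf("  up-regulated %s (%s), down-regulated %s (%s)",
              fmt_int(cl$n_up), fmt_pct(cl$pct_up),
              fmt_int(cl$n_down), fmt_pct(cl$pct_down)))
  }
  if (!is.null(report$concordance))
    lines <- c(lines, sprintf(
      "qPCR concordance: %s / %s (%s)",
      fmt_int(report$concordance$n_concordant),
      fmt_int(report$concordance$n_total),
      fmt_pct(report$concordance$pct_concordant)))
  lines
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}
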