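#' Per-candidate temporal sign profiles
#'
#' Builds each candidate gene's direction triple s = (s1, s2, s3) over the
#' three treatment timepoints (+1 up, -1 down, 0 no change in ETHt/CKt),
#' plus its log2 fold-change profile for clustering and heatmaps.
#'
#' @param responsive A \code{responsive_set}.
#' @param candidates Character vector of candidate gene ids (or a
#'   \code{candidate_set}); must be a subset of the responsive union.
#' @param degs Optional named list of \code{deg_table}s (as from
#'   \code{\link{call_all_degs}}) supplying the log2 fold-change profile;
#'   if omitted the profile is the sign triple itself.
#' @return Data frame of class \code{sign_profiles} with columns
#'   \code{gene_id, s1, s2, s3, lfc1, lfc2, lfc3}.
#' @export
sign_profiles <- function(responsive, candidates, degs = NULL) {
  stopifnot(inherits(responsive, "responsive_set"))
  if (inherits(candidates, "candidate_set"))
    candidates <- candidates$candidates
  u <- responsive$union
  missing <- setdiff(candidates, u$gene_id)
  if (length(missing))
    stopf("candidate gene(s) not in responsive union: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  idx <- match(candidates, u$gene_id)
  as_sign <- function(d) ifelse(d == "up", 1L, ifelse(d == "down", -1L, 0L))
  out <- data.frame(gene_id = candidates,
                    s1 = as_sign(u$dir_1d[idx]),
                    s2 = as_sign(u$dir_2d[idx]),
                    s3 = as_sign(u$dir_3d[idx]), row.names = NULL)
  for (t in 1:3) {
    col <- paste0("lfc", t)
    if (is.null(degs)) {
      out[[col]] <- as.numeric(out[[paste0("s", t)]])
    } else {
      d <- degs[[sprintf("CK%d_vs_ETH%d", t, t)]]
      out[[col]] <- d$log2fc[match(candidates, d$gene_id)]
    }
  }
  class(out) <- c("sign_profiles", "data.frame")
  out
}

#' Temporal response group of a sign profile
#'
#' Deterministic total rule over nonzero sign triples:
#' \itemize{
#'   \item Group IV (constant-responsive): s1 != 0 and s3 != 0 with the
#'     same sign — an early change that persists to day 3 (day-2 status
#'     unconstrained).
#'   \item Group I (early-responsive): s1 != 0 and not Group IV — an early
#'     change that is transient or reverses.
#'   \item Group II (middle-responsive): s1 = 0 and s2 != 0 — first change
#'     at day 2.
#'   \item Group III (late-responsive): s1 = s2 = 0 and s3 != 0 — first
#'     change at day 3.
#' }
#' The four predicates cover and partition all 26 nonzero triples.
#'
#' @param profiles A \code{sign_profiles} data frame (or any data frame
#'   with integer columns s1, s2, s3 in \{-1, 0, 1\}).
#' @return Data frame of class \code{group_assignment}: columns
#'   \code{gene_id, s1, s2, s3, pattern, group} (group in
#'   \code{c("I","II","III","IV")}).
#' @export
assign_group <- function(profiles) {
  s1 <- profiles$s1; s2 <- profiles$s2; s3 <- profiles$s3
  if (any(abs(c(s1, s2, s3)) > 1))
    stopf("signs must be -1, 0 or +1")
  if (any(s1 == 0 & s2 == 0 & s3 == 0))
    stopf("all-zero sign profile: not a candidate gene")
  g4 <- s1 != 0 & s3 != 0 & sign(s1) == sign(s3)
  g1 <- s1 != 0 & !g4
  g2 <- s1 == 0 & s2 != 0
  g3 <- s1 == 0 & s2 == 0 & s3 != 0
  group <- character(length(s1))
  group[g1] <- "I"; group[g2] <- "II"; group[g3] <- "III"; group[g4] <- "IV"
  sym <- c("-", "0", "+")
  pattern <- paste0("(", sym[s1 + 2], ",", sym[s2 + 2], ",", sym[s3 + 2], ")")
  out <- data.frame(gene_id = profiles$gene_id, s1 = s1, s2 = s2, s3 = s3,
                    pattern = pattern, group = group, row.names = NULL)
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Sub-cluster each temporal group
#'
#' Default mode partitions each group by exact sign-pattern string, with
#' labels ordered lexicographically within the group (1A, 1B, ... for
#' Group I, 2A ... for Group II, and so on). The alternative mode runs
#' average-linkage hierarchical clustering (Euclidean distance) on the
#' log2 fold-change profiles and cuts the tree to a requested number of
#' clusters per group; cluster labels follow first appearance in gene
#' order. Both modes are deterministic.
#'
#' @param assignments A \code{group_assignment}.
#' @param profiles The matching \code{sign_profiles} (needed for
#'   \code{method = "hclust"}).
#' @param method "pattern" (default) or "hclust".
#' @param k For "hclust": requested cluster count per group — a single
#'   number or a vector named by group; must not exceed the group size.
#' @return \code{assignments} with an added \code{subcluster} column.
#' @export
subcluster <- function(assignments, profiles = NULL,
                       method = c("pattern", "hclust"), k = 2) {
  method <- match.arg(method)
  arabic <- c(I = "1", II = "2", III = "3", IV = "4")
  out <- assignments
  out$subcluster <- NA_character_
  for (g in unique(assignments$group)) {
    in_g <- which(assignments$group == g)
    if (method == "pattern") {
      pats <- sort(unique(assignments$pattern[in_g]), method = "radix")
      idx <- match(assignments$pattern[in_g], pats)
    } else {
      if (is.null(profiles))
        stopf("hclust mode needs the sign_profiles log2fc columns")
      kg <- if (length(k) > 1) k[[g]] else k
      if (kg > length(in_g))
        stopf("requested %d clusters for group %s of size %d",
              kg, g, length(in_g))
      m <- as.matrix(profiles[match(assignments$gene_id[in_g],
                                    profiles$gene_id),
                              c("lfc1", "lfc2", "lfc3")])
      cl <- if (length(in_g) == 1) 1L else
        stats::cutree(stats::hclust(stats::dist(m), method = "average"), kg)
      idx <- match(cl, unique(cl))  # relabel by first appearance
    }
    out$subcluster[in_g] <- paste0(arabic[[g]], LETTERS[idx])
  }
  out
}

#' Summary accounting of the temporal classification
#'
#' Counts per group and sub-cluster; per-timepoint up/down counts by onset
#' (a gene's onset is its first nonzero timepoint, its direction the sign
#' there); overall up/down totals; percentages as 100 * part/total rounded
#' half-up to two decimals; and the heatmap-ready log2 fold-change matrix
#' ordered by group, then sub-cluster, then gene id.
#'
#' @param assignments A \code{group_assignment} (with \code{subcluster}
#'   column if \code{\link{subcluster}} has been run).
#' @param profiles The matching \code{sign_profiles} (optional; required
#'   for the heatmap matrix).
#' @return List of class \code{classification_summary}: \code{n_total},
#'   \code{group_counts}, \code{subcluster_counts}, \code{onset_up},
#'   \code{onset_down} (each length 3, by timepoint), \code{n_up},
#'   \code{n_down}, \code{pct_up}, \code{pct_down}, \code{group_pct},
#'   \code{pct_day1}, and \code{heatmap} (matrix or NULL).
#' @export
summarize_classification <- function(assignments, profiles = NULL) {
  if (nrow(assignments) == 0) stopf("no assignments to summarise")
  n <- nrow(assignments)
  groups <- factor(assignments$group, levels = c("I", "II", "III", "IV"))
  group_counts <- table(groups)
  s <- as.matrix(assignments[c("s1", "s2", "s3")])
  onset <- apply(s != 0, 1, which.max)
  onset_sign <- s[cbind(seq_len(n), onset)]
  onset_up <- vapply(1:3, function(t) sum(onset == t & onset_sign > 0), 0L)
  onset_down <- vapply(1:3, function(t) sum(onset == t & onset_sign < 0), 0L)
  heat <- NULL
  if (!is.null(profiles)) {
    sub <- if ("subcluster" %in% names(assignments))
      assignments$subcluster else ""
    ord <- order(as.integer(groups), sub, assignments$gene_id)
    heat <- as.matrix(profiles[match(assignments$gene_id[ord],
                                     profiles$gene_id),
                               c("lfc1", "lfc2", "lfc3")])
    rownames(heat) <- assignments$gene_id[ord]
    colnames(heat) <- c("1d", "2d", "3d")
  }
  structure(list(
    n_total = n,
    group_counts = stats::setNames(as.integer(group_counts),
                                   names(group_counts)),
    subcluster_counts = if ("subcluster" %in% names(assignments))
      table(assignments$subcluster) else NULL,
    onset_up = onset_up, onset_down = onset_down,
    n_up = sum(onset_sign > 0), n_down = sum(onset_sign < 0),
    pct_up = pct(sum(onset_sign > 0), n),
    pct_down = pct(sum(onset_sign < 0), n),
    group_pct = pct(as.integer(group_counts), n),
    pct_day1 = pct(sum(onset == 1), n),
    heatmap = heat), class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("classification_summary: %d candidate genes\n", x$n_total))
  cat(sprintf("  Group %-3s %5d (%.2f%%)\n", names(x$group_counts),
              x$group_counts, x$group_pct), sep = "")
  cat(sprintf("  day-1 responders: %.2f%%; up %d (%.2f%%), down %d (%.2f%%)\n",
              x$pct_day1, x$n_up, x$pct_up, x$n_down, x$pct_down))
  invisible(x)
}

#' Write assignments and the heatmap matrix as TSV
#'
#' @param assignments A \code{group_assignment} with subcluster labels.
#' @param summary A \code{classification_summary} (for the heatmap
#'   matrix); optional.
#' @param path Output path for the assignment table.
#' @param heatmap_path Optional output path for the heatmap matrix.
#' @return \code{path}, invisibly.
#' @export
write_classification <- function(assignments, summary = NULL, path,
                                 heatmap_path = NULL) {
  write_tsv(assignments, path)
  if (!is.null(heatmap_path) && !is.null(summary$heatmap)) {
    df <- data.frame(gene_id = rownames(summary$heatmap),
                     summary$heatmap, check.names = FALSE)
    write_tsv(df, heatmap_path)
  }
  invisible(path)
}
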