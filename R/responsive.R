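#' Remove control-drift background from a treatment DEG list
#'
#' Genes differentially expressed between CK0 and CKt reflect time effects
#' in the untreated control; they are excluded (by gene id, regardless of
#' direction, unless \code{direction_aware}) from the CKt-vs-ETHt DEG list
#' to leave treatment-specific calls.
#'
#' @param treatment_degs,control_degs \code{deg_table}s over the same gene
#'   universe (the CKt-vs-ETHt and CK0-vs-CKt comparisons).
#' @param direction_aware If TRUE, exclusion requires the control call to
#'   share the treatment call's direction (default FALSE: exclusion is by
#'   gene id only).
#' @return Data frame with columns \code{gene_id}, \code{direction}
#'   ("up"/"down", carried from the treatment comparison).
#' @export
subtract_background <- function(treatment_degs, control_degs,
                                direction_aware = FALSE) {
  if (!setequal(treatment_degs$gene_id, control_degs$gene_id))
    stopf("treatment and control DEG lists cover different gene universes")
  tr <- treatment_degs[treatment_degs$direction != "none",
                       c("gene_id", "direction")]
  ct <- control_degs[control_degs$direction != "none",
                     c("gene_id", "direction")]
  drop <- if (direction_aware) {
    paste(tr$gene_id, tr$direction) %in% paste(ct$gene_id, ct$direction)
  } else {
    tr$gene_id %in% ct$gene_id
  }
  data.frame(gene_id = tr$gene_id[!drop], direction = tr$direction[!drop],
             row.names = NULL)
}

#' Build the treatment-responsive gene set
#'
#' Applies background subtraction at each timepoint (ETHt/CKt) and takes
#' the union across the three timepoints: the ethephon-responsive gene
#' set, each member carrying its per-timepoint direction vector.
#'
#' @param degs Named list of the six \code{deg_table}s, with the names
#'   produced by \code{\link{dta_pairs}} / \code{\link{call_all_degs}}.
#' @param direction_aware Passed to \code{\link{subtract_background}}.
#' @return An object of class \code{responsive_set}: list with
#'   \code{per_timepoint} (list of three gene_id/direction data frames,
#'   named "1","2","3") and \code{union} (data frame gene_id, dir_1d,
#'   dir_2d, dir_3d with values "up"/"down"/"none").
#' @export
build_responsive <- function(degs, direction_aware = FALSE) {
  need <- names(dta_pairs())
  if (!all(need %in% names(degs)))
    stopf("missing comparison(s): %s",
          paste(setdiff(need, names(degs)), collapse = ", "))
  per <- lapply(1:3, function(t) {
    subtract_background(degs[[sprintf("CK%d_vs_ETH%d", t, t)]],
                        degs[[sprintf("CK0_vs_CK%d", t)]],
                        direction_aware = direction_aware)
  })
  names(per) <- as.character(1:3)
  ids <- sort(unique(unlist(lapply(per, `[[`, "gene_id"))),
              method = "radix")
  dirs <- vapply(per, function(d) {
    v <- rep("none", length(ids))
    v[match(d$gene_id, ids)] <- d$direction
    v
  }, character(length(ids)))
  union <- data.frame(gene_id = ids, row.names = NULL)
  if (length(ids) == 0) {
    union$dir_1d <- union$dir_2d <- union$dir_3d <- character(0)
  } else {
    dirs <- matrix(dirs, nrow = length(ids))
    union$dir_1d <- dirs[, 1]; union$dir_2d <- dirs[, 2]
    union$dir_3d <- dirs[, 3]
  }
  structure(list(per_timepoint = per, union = union),
            class = "responsive_set")
}

#' @export
print.responsive_set <- function(x, ...) {
  sizes <- vapply(x$per_timepoint, nrow, 0L)
  cat(sprintf(
    "responsive_set: |ETH1/CK1| = %d, |ETH2/CK2| = %d, |ETH3/CK3| = %d, union = %d\n",
    sizes[1], sizes[2], sizes[3], nrow(x$union)))
  invisible(x)
}

#' Write a responsive set's union table as TSV
#'
#' @param x A \code{responsive_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_responsive <- function(x, path) {
  stopifnot(inherits(x, "responsive_set"))
  write_tsv(x$union, path)
}
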