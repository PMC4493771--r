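#' Configuration of the synthetic seven-library experiment
#'
#' Parameterises the structure the tag-profiling design assumes: seven
#' unreplicated pooled-replicate libraries (CK0-CK3, ETH1-ETH3) over a
#' shared gene universe, with planted temporal treatment effects and
#' optional control drift.
#'
#' Temporal patterns are three-character strings over \code{+ - 0}, one
#' character per treatment timepoint (1, 2, 3 d); e.g. \code{"+00"} is an
#' early transient up-regulation, \code{"---"} a persistent
#' down-regulation. \code{planted_fractions} maps pattern to the fraction
#' of genes planted with it; the remainder are null genes.
#'
#' @param n_genes Number of genes (> 0).
#' @param library_depth Target total assigned reads per library (> 0).
#' @param gene_length_range Min/max gene length in bp.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 degenerates to Poisson.
#' @param planted_fractions Named numeric vector, pattern -> fraction;
#'   fractions must sum to <= 1.
#' @param effect_log2fc Planted effect magnitude in log2 units, >= 2 so
#'   planted genes carry at least the four-fold gate magnitude
#'   (default 3, i.e. eight-fold).
#' @param control_drift_fraction Fraction of null genes carrying a random
#'   time effect in the untreated controls CK1-CK3 (default 0).
#' @param control_drift_log2fc Magnitude of the control drift in log2
#'   units (default 2.5).
#' @param annotation List with \code{n_terms}, \code{term_size_range},
#'   \code{n_enriched_terms}, \code{enrichment_strength} (in [0, 1]).
#' @param seed Master seed; all sub-stages derive deterministic sub-seeds
#'   from it.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 20000,
                       library_depth = 4.5e6,
                       gene_length_range = c(200, 5000),
                       dispersion = 0.05,
                       planted_fractions = c(
                         "+00" = 0.010, "-00" = 0.020,
                         "0+0" = 0.002, "0-0" = 0.002,
                         "00+" = 0.003, "00-" = 0.003,
                         "+++" = 0.005, "---" = 0.010,
                         "+0+" = 0.002, "-0-" = 0.003),
                       effect_log2fc = 3,
                       control_drift_fraction = 0,
                       control_drift_log2fc = 2.5,
                       annotation = list(n_terms = 100,
                                         term_size_range = c(10, 200),
                                         n_enriched_terms = 10,
                                         enrichment_strength = 0.8),
                       seed = 1) {
  if (n_genes < 1) stopf("n_genes must be positive")
  if (library_depth < 1) stopf("library_depth must be positive")
  if (length(gene_length_range) != 2 ||
      gene_length_range[1] > gene_length_range[2] ||
      gene_length_range[1] < 1)
    stopf("gene_length_range must be a non-empty range of positive lengths")
  if (dispersion < 0) stopf("dispersion must be non-negative")
  if (length(planted_fractions)) {
    if (is.null(names(planted_fractions)) ||
        !all(grepl("^[+0-]{3}$", names(planted_fractions))))
      stopf("planted_fractions names must be 3-character patterns over +,-,0")
    if (any(names(planted_fractions) == "000"))
      stopf("pattern '000' is the null pattern; omit it")
    if (any(planted_fractions < 0) || sum(planted_fractions) > 1)
      stopf("planted fractions must be non-negative and sum to <= 1")
  }
  if (effect_log2fc < 2)
    stopf("effect_log2fc must be >= 2 (the four-fold gate magnitude)")
  if (control_drift_fraction < 0 || control_drift_fraction > 1)
    stopf("control_drift_fraction must be in [0, 1]")
  ann <- annotation
  if (ann$n_terms < 0 || ann$n_enriched_terms > ann$n_terms)
    stopf("annotation: need 0 <= n_enriched_terms <= n_terms")
  if (length(ann$term_size_range) != 2 ||
      ann$term_size_range[1] > ann$term_size_range[2] ||
      ann$term_size_range[1] < 1)
    stopf("annotation: term_size_range must be a non-empty positive range")
  if (ann$enrichment_strength < 0 || ann$enrichment_strength > 1)
    stopf("annotation: enrichment_strength must be in [0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 library_depth = library_depth,
                 gene_length_range = as.integer(gene_length_range),
                 dispersion = dispersion,
                 planted_fractions = planted_fractions,
                 effect_log2fc = effect_log2fc,
                 control_drift_fraction = control_drift_fraction,
                 control_drift_log2fc = control_drift_log2fc,
                 annotation = ann, seed = as.integer(seed)),
            class = "sim_config")
}

pattern_lfc <- function(pattern, effect) {
  s <- match(strsplit(pattern, "")[[1]], c("-", "0", "+")) - 2L
  s * effect
}

# NB sampling with mean mu and variance mu + dispersion*mu^2;
# dispersion 0 -> Poisson
sample_counts <- function(mu, dispersion) {
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}

#' Generate a synthetic seven-library tag-count experiment
#'
#' Baseline expected expression is drawn log-uniform over four decades so
#' the dynamic range covers both low-count genes (stressing the exact
#' test) and high-count genes, then scaled so control libraries hit the
#' target depth in expectation. The four control libraries share the
#' baseline (plus sampling noise, plus drift where configured); each
#' treated library ETHt multiplies the baseline by 2^(planted log2 effect
#' at t). Control drift genes follow their drifted trajectory in CK1-CK3
#' only — the treated tissue does not track the control's time effects, so
#' drift genes surface in both the CK0-vs-CKt and CKt-vs-ETHt comparisons
#' and genuinely exercise background subtraction.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{counts} (a \code{count_matrix}) and
#'   \code{truth} (data frame of class \code{synthetic_truth}: gene_id,
#'   pattern ("null" or the planted pattern), lfc1-lfc3, drift flag,
#'   drift1-drift3, baseline_mean — the expected control count).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  lengths <- with_seed(derive_seed(config$seed, "lengths"),
    sample(config$gene_length_range[1]:config$gene_length_range[2], n,
           replace = TRUE))
  w <- with_seed(derive_seed(config$seed, "baseline"), 10^stats::runif(n, -2, 2))
  mu0 <- w / sum(w) * config$library_depth

  # plant temporal patterns on disjoint random gene sets
  pattern <- rep("null", n)
  lfc <- matrix(0, n, 3)
  pf <- config$planted_fractions
  if (length(pf)) {
    n_per <- round(pf * n)
    picked <- with_seed(derive_seed(config$seed, "patterns"),
                        sample(n, sum(n_per)))
    at <- 0
    for (i in seq_along(n_per)) {
      if (n_per[i] == 0) next
      idx <- picked[(at + 1):(at + n_per[i])]
      at <- at + n_per[i]
      pattern[idx] <- names(pf)[i]
      lfc[idx, ] <- matrix(pattern_lfc(names(pf)[i], config$effect_log2fc),
                           n_per[i], 3, byrow = TRUE)
    }
  }

  # control drift on null genes only, one signed effect per gene applied
  # from its (random) onset timepoint onward
  drift <- matrix(0, n, 3)
  if (config$control_drift_fraction > 0) {
    nulls <- which(pattern == "null")
    n_drift <- round(config$control_drift_fraction * length(nulls))
    if (n_drift > 0) {
      dd <- with_seed(derive_seed(config$seed, "drift"), {
        idx <- sample(nulls, n_drift)
        sgn <- sample(c(-1, 1), n_drift, replace = TRUE)
        onset <- sample(1:3, n_drift, replace = TRUE)
        list(idx = idx, sgn = sgn, onset = onset)
      })
      for (t in 1:3) {
        on <- dd$onset <= t
        drift[dd$idx[on], t] <- dd$sgn[on] * config$control_drift_log2fc
      }
    }
  }

  mu <- cbind(CK0 = mu0,
              CK1 = mu0 * 2^drift[, 1],
              CK2 = mu0 * 2^drift[, 2],
              CK3 = mu0 * 2^drift[, 3],
              ETH1 = mu0 * 2^lfc[, 1],
              ETH2 = mu0 * 2^lfc[, 2],
              ETH3 = mu0 * 2^lfc[, 3])
  counts <- vapply(DTA_LIBRARIES, function(lib)
    with_seed(derive_seed(config$seed, paste0("counts:", lib)),
              as.numeric(sample_counts(mu[, lib], config$dispersion))),
    numeric(n))
  if (n == 1)
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(NULL, DTA_LIBRARIES))
  truth <- data.frame(gene_id = gene_id, pattern = pattern,
                      lfc1 = lfc[, 1], lfc2 = lfc[, 2], lfc3 = lfc[, 3],
                      drift = drift[, 1] != 0 | drift[, 2] != 0 |
                        drift[, 3] != 0,
                      drift1 = drift[, 1], drift2 = drift[, 2],
                      drift3 = drift[, 3],
                      baseline_mean = mu0, row.names = NULL)
  class(truth) <- c("synthetic_truth", "data.frame")
  list(counts = count_matrix(counts, gene_id, lengths), truth = truth)
}

#' Generate a synthetic term-to-gene annotation map
#'
#' Term sizes are uniform over the configured range. The first
#' \code{n_enriched_terms} terms are enriched: a fraction
#' \code{enrichment_strength} of each one's members is drawn from the
#' planted (non-null) genes, the rest uniformly from the remaining genes;
#' at strength 1 the whole term comes from non-null genes. Non-enriched
#' terms draw uniformly from all genes.
#'
#' @param config A \code{sim_config}.
#' @param truth The \code{synthetic_truth} from the same experiment.
#' @param vocabulary "GO-like" or "KEGG-like" (also seeds the map, so the
#'   two vocabularies differ).
#' @return Data frame (term_id, gene_id) with attributes
#'   \code{vocabulary} and \code{enriched_terms} (character vector of the
#'   planted-enrichment term ids).
#' @export
generate_annotation <- function(config, truth,
                                vocabulary = c("GO-like", "KEGG-like")) {
  stopifnot(inherits(config, "sim_config"))
  vocabulary <- match.arg(vocabulary)
  ann <- config$annotation
  if (ann$term_size_range[2] > config$n_genes)
    stopf("term_size_range exceeds the number of genes")
  prefix <- if (vocabulary == "GO-like") "GO:%04d" else "ko%04d"
  nonnull <- truth$gene_id[truth$pattern != "null"]
  all_genes <- truth$gene_id
  with_seed(derive_seed(config$seed, paste0("annotation:", vocabulary)), {
    sizes <- sample(ann$term_size_range[1]:ann$term_size_range[2],
                    ann$n_terms, replace = TRUE)
    members <- lapply(seq_len(ann$n_terms), function(i) {
      if (i <= ann$n_enriched_terms && length(nonnull) > 0) {
        n_pl <- min(round(ann$enrichment_strength * sizes[i]),
                    length(nonnull))
        pl <- sample(nonnull, n_pl)
        rest <- sample(setdiff(all_genes, pl), sizes[i] - n_pl)
        c(pl, rest)
      } else {
        sample(all_genes, sizes[i])
      }
    })
    term_id <- sprintf(prefix, seq_len(ann$n_terms))
    out <- data.frame(
      term_id = rep(term_id, lengths(members)),
      gene_id = unlist(members), row.names = NULL)
    attr(out, "vocabulary") <- vocabulary
    attr(out, "enriched_terms") <- term_id[seq_len(ann$n_enriched_terms)]
    out
  })
}

#' Generate a synthetic qPCR Ct table with known truth
#'
#' Targets are sampled from the planted (non-null) genes. Each target's
#' baseline Ct is uniform over 18-30 cycles; its Ct at treatment
#' timepoint t is shifted by minus the planted log2 effect (one doubling
#' per cycle) plus Gaussian noise. The two reference genes are constant
#' in expectation across samples.
#'
#' @param truth A \code{synthetic_truth}.
#' @param n_target_genes Number of target genes (default 41); must not
#'   exceed the number of non-null genes.
#' @param noise_sd Gaussian Ct noise, cycles (default 0.2).
#' @param seed Seed for target selection and noise.
#' @param n_replicates Replicates per gene and sample (default 3).
#' @return Ct data frame (gene_id, sample, replicate, ct, is_reference)
#'   with attribute \code{targets}.
#' @export
generate_ct_table <- function(truth, n_target_genes = 41, noise_sd = 0.2,
                              seed = 1, n_replicates = 3) {
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  nonnull <- truth[truth$pattern != "null", , drop = FALSE]
  if (n_target_genes > nrow(nonnull))
    stopf("n_target_genes (%d) exceeds the %d non-null genes",
          n_target_genes, nrow(nonnull))
  samples <- c("0d", "1d", "2d", "3d")
  refs <- data.frame(gene_id = c("EF1a", "GAPDH"), base_ct = c(20, 22))
  with_seed(derive_seed(seed, "ct"), {
    tg <- nonnull[sample(nrow(nonnull), n_target_genes), , drop = FALSE]
    base <- stats::runif(n_target_genes, 18, 30)
    rows <- list()
    for (i in seq_len(n_target_genes)) {
      shift <- c(0, -tg$lfc1[i], -tg$lfc2[i], -tg$lfc3[i])
      for (s in seq_along(samples)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = tg$gene_id[i], sample = samples[s],
          replicate = seq_len(n_replicates),
          ct = base[i] + shift[s] +
            stats::rnorm(n_replicates, 0, noise_sd),
          is_reference = FALSE)
      }
    }
    for (r in seq_len(nrow(refs))) {
      for (s in samples) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = refs$gene_id[r], sample = s,
          replicate = seq_len(n_replicates),
          ct = refs$base_ct[r] + stats::rnorm(n_replicates, 0, noise_sd),
          is_reference = TRUE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "targets") <- tg$gene_id
    out
  })
}

#' Write a synthetic truth table as JSON
#'
#' @param truth A \code{synthetic_truth}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(as.data.frame(unclass(truth)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
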