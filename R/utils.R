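#' @keywords internal
"_PACKAGE"

#' Library labels of the seven-library abscission time-course design
#'
#' Untreated control libraries at 0, 1, 2 and 3 days (CK0-CK3) and
#' ethephon-treated libraries at 1, 2 and 3 days (ETH1-ETH3).
#'
#' @format Character vector of length 7.
#' @export
DTA_LIBRARIES <- c("CK0", "CK1", "CK2", "CK3", "ETH1", "ETH2", "ETH3")

#' The six fixed library comparisons of the time-course design
#'
#' Three control drift comparisons (CK0 vs CK1/CK2/CK3) and three
#' treatment-vs-control comparisons at matched timepoints (CKt vs ETHt).
#' Each element is \code{c(reference, test)}.
#'
#' @return Named list of length-2 character vectors; names are
#'   \code{"<ref>_vs_<test>"}.
#' @export
dta_pairs <- function() {
  pairs <- list(
    c("CK0", "CK1"), c("CK0", "CK2"), c("CK0", "CK3"),
    c("CK1", "ETH1"), c("CK2", "ETH2"), c("CK3", "ETH3")
  )
  names(pairs) <- vapply(pairs, function(p) paste0(p[1], "_vs_", p[2]), "")
  pairs
}

# round-half-up, matching the presentation convention of the library
# bookkeeping tables (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # nudge by a relative epsilon so values stored as e.g. 87.114999999...
  # that are exactly representable halves still round up
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param num,den Non-negative numerators and positive denominators.
#' @param digits Decimal places kept (default 2, the convention of the
#'   sequencing bookkeeping tables).
#' @return Numeric percentages.
#' @export
pct <- function(num, den, digits = 2) {
  if (any(den <= 0)) stop("percentage denominator must be positive")
  round_half_up(100 * num / den, digits)
}

# deterministic sub-seed derivation: one master seed, stable per section
# label, kept below 2^31
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# evaluate expr under a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a data frame as tab-separated text
#'
#' @param x A data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

fmt_int <- function(x) formatC(x, format = "d", big.mark = ",")
fmt_pct <- function(x) sprintf("%.2f%%", x)
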