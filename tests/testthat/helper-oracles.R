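# Independent brute-force oracles, coded from definitions only.

# Audic-Claverie two-sided p by direct log-gamma pmf summation over the
# conditional distribution p(y'|x), y' = 0..ymax.
ac_oracle <- function(x, y, n1, n2, ymax = NULL) {
  r <- n2 / n1
  if (is.null(ymax))
    ymax <- ceiling((x + 1) * r + 20 * sqrt((x + 1) * r * (1 + r)) + 1000)
  yy <- 0:ymax
  logpmf <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
    lgamma(yy + 1) - (x + yy + 1) * log(1 + r)
  pmf <- exp(logpmf)
  lower <- cumsum(pmf)[y + 1]
  upper <- rev(cumsum(rev(pmf)))[y + 1]
  min(1, 2 * min(lower, upper))
}

# Benjamini-Hochberg step-up from the definition: adj_(i) over sorted
# p-values is min over j >= i of m * p_(j) / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# a tiny count_matrix over the seven-library design
toy_counts <- function(counts, gene_id = sprintf("g%d", seq_len(nrow(counts))),
                       length_bp = rep(1000L, nrow(counts))) {
  colnames(counts) <- dtakit::DTA_LIBRARIES
  count_matrix(counts, gene_id, length_bp)
}

extdata <- function(f) system.file("extdata", f, package = "dtakit")

# expand a pattern -> count table into per-gene sign profiles
profiles_from_pattern_counts <- function(tab) {
  sgn <- function(ch) c("-" = -1L, "0" = 0L, "+" = 1L)[[ch]]
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    ch <- strsplit(tab$pattern[i], "")[[1]]
    data.frame(s1 = sgn(ch[1]), s2 = sgn(ch[2]), s3 = sgn(ch[3]),
               n = tab$n[i])
  }))
  out <- rows[rep(seq_len(nrow(rows)), rows$n), c("s1", "s2", "s3")]
  out$gene_id <- sprintf("F%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("gene_id", "s1", "s2", "s3")]
}
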