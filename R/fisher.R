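#' Fast Fisher exact test for 2x2 tables
#'
#' Exact hypergeometric test on the table
#' \preformatted{  a  b
#'   c  d}
#' vectorised over tables. The two-sided p-value sums all tables (with the
#' same margins) whose point probability does not exceed that of the
#' observed table times \code{1 + 1e-7}, the same tie rule as
#' \code{stats::fisher.test}. One-sided alternatives refer to the odds
#' ratio of the first row, i.e. \code{"greater"} tests enrichment of
#' \code{a} relative to its margin.
#'
#' Written as a thin vectorised layer over \code{stats::dhyper} because the
#' variant-filtering and cohort-comparison paths evaluate thousands of
#' tables in bulk; agrees with \code{stats::fisher.test} (see tests).
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to common length).
#' @param alternative "two.sided", "greater" or "less".
#' @return Numeric vector of p-values.
#' @export
fisher_p <- function(a, b, c, d, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop("table entries must be non-negative and non-missing")
  }
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]              # row 1 margin (white balls)
    m2 <- c[i] + d[i]              # row 2 margin (black balls)
    k  <- a[i] + c[i]              # column 1 margin (drawn)
    lo <- max(0, k - m2); hi <- min(k, m1)
    x  <- lo:hi
    dens <- stats::dhyper(x, m1, m2, k)
    dobs <- dens[x == a[i]]
    p[i] <- switch(alternative,
      two.sided = sum(dens[dens <= dobs * (1 + 1e-7)]),
      greater   = sum(dens[x >= a[i]]),
      less      = sum(dens[x <= a[i]]))
    if (p[i] > 1) p[i] <- 1
  }
  p
}
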