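# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: Fisher probabilities come from binomial
# coefficients, not dhyper.

# exact hypergeometric enumeration for one 2x2 table
fisher_oracle <- function(a, b, c, d, alternative = "two.sided") {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  dens <- choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k)
  dobs <- dens[x == a]
  p <- switch(alternative,
              two.sided = sum(dens[dens <= dobs * (1 + 1e-7)]),
              greater = sum(dens[x >= a]),
              less = sum(dens[x <= a]))
  min(p, 1)
}

# oracle p-values for every table with the given row margins, both
# alternatives; returns data frame over (a, c)
fisher_oracle_margins <- function(m1, m2) {
  out <- expand.grid(a = 0:m1, c = 0:m2)
  out$two.sided <- mapply(function(a, c)
    fisher_oracle(a, m1 - a, c, m2 - c, "two.sided"), out$a, out$c)
  out$greater <- mapply(function(a, c)
    fisher_oracle(a, m1 - a, c, m2 - c, "greater"), out$a, out$c)
  out
}

rdirichlet_test <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

# brute-force best size-k subset of reference signatures by NNLS
# reconstruction cosine
best_subset_cosine <- function(v, catalog, k) {
  subsets <- utils::combn(colnames(catalog), k, simplify = FALSE)
  cosines <- vapply(subsets, function(s) {
    fit <- pracma::lsqnonneg(catalog[, s, drop = FALSE], v)
    rec <- catalog[, s, drop = FALSE] %*% fit$x
    sum(v * rec) / (sqrt(sum(v^2)) * sqrt(sum(rec^2)))
  }, numeric(1))
  sort(subsets[[which.max(cosines)]])
}

# a minimal clean SNV record passing every filter
clean_snv <- function(n = 1L, sample_id = "S1") {
  data.frame(sample_id = sample_id, chrom = "chr1", pos = seq_len(n),
             ref = "C", alt = "T", variant_class = "SNV",
             t_alt = 30L, t_ref = 70L, n_alt = 0L, n_ref = 100L,
             alt_fwd = 15L, alt_rev = 15L, ref_fwd = 35L, ref_rev = 35L,
             site_bq = 35, flank_bq = 35, alt_mq = 60,
             stringsAsFactors = FALSE)
}
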