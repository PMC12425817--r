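test_that("compare_frequencies flags nothing for identical cohorts", {
  a <- list(n = 100, counts = c(TP53 = 80, PIK3CA = 10))
  r <- compare_frequencies(a, a)
  expect_equal(r$p, rep(1, nrow(r)), tolerance = 1e-9)
  expect_false(any(r$flagged))
  expect_error(compare_frequencies(list(n = 0, counts = c(A = 0)), a),
               "positive")
  expect_error(compare_frequencies(list(n = 5, counts = c(A = 9)), a),
               "exceed")
})

test_that("a TP53-like contrast is strongly significant", {
  # 437/462 vs 218/279: enumeration oracle p = 3.4e-11
  expect_lt(fisher_oracle(437, 25, 218, 61), 1e-9)
  aa <- list(n = 462, counts = c(TP53 = 437))
  chn <- list(n = 279, counts = c(TP53 = 218))
  r <- compare_frequencies(aa, chn)
  expect_lt(r$p, 1e-9)
  expect_true(r$flagged)
})

test_that("q-values respect the Benjamini-Hochberg step-up structure", {
  set.seed(23)
  a <- list(n = 200, counts = setNames(rbinom(40, 60, 0.3), paste0("g", 1:40)))
  b <- list(n = 300, counts = setNames(rbinom(40, 70, 0.25), paste0("g", 1:40)))
  r <- compare_frequencies(a, b)
  ord <- order(r$p)
  expect_true(all(diff(r$q[ord]) >= -1e-12))
  # q-values match the textbook step-up formula computed independently
  m <- nrow(r)
  ps <- sort(r$p)
  q_manual <- rev(cummin(rev(pmin(1, ps * m / seq_len(m)))))
  expect_equal(sort(r$q), q_manual, tolerance = 1e-12)
  # the flagged set is exactly the BH rejection set at 0.10
  k_star <- max(c(0L, which(ps < 0.10 * seq_len(m) / m)))
  expected_flag <- if (k_star == 0L) rep(FALSE, m) else r$p <= ps[k_star]
  expect_equal(r$flagged, expected_flag)
})

test_that("germline test picks chi-square or Fisher by expected counts", {
  eq <- germline_vs_reference(50, 1000, 5000, 100000)
  expect_gt(eq$p, 0.9)
  expect_equal(eq$method, "chisq")
  rare <- germline_vs_reference(5, 924, 10, 100000)
  expect_equal(rare$method, "fisher")
  expect_lt(rare$p, 1e-4)
  expect_lt(germline_vs_reference(5, 924, 10, 100000,
                                  alternative = "greater")$p, 1e-4)
  # where both are valid they agree within 2-fold
  both_f <- stats::fisher.test(matrix(c(60, 940, 400, 9600), 2,
                                      byrow = TRUE))$p.value
  both_c <- suppressWarnings(
    stats::chisq.test(matrix(c(60, 940, 400, 9600), 2, byrow = TRUE))$p.value)
  expect_lt(abs(log(both_f / both_c)), log(2))
  expect_error(germline_vs_reference(1, 0, 1, 10), "positive")
})

test_that("threshold_cn maps integer CN to GISTIC-style values monotonically", {
  expect_equal(threshold_cn(c(0, 1, 2, 3, 4, 5, 6, 12)),
               c(-2L, -1L, 0L, 1L, 1L, 2L, 2L, 2L))
  expect_true(all(diff(threshold_cn(0:20)) >= 0))
  expect_equal(threshold_cn(4, high_amp_min = 4L), 2L)
  expect_error(threshold_cn(-1), "non-negative")
})

test_that("cd274_class distinguishes gain from high-level amplification", {
  expect_equal(cd274_class(c(-2L, -1L, 0L, 1L, 2L)),
               c("neutral", "neutral", "neutral", "gain", "high_amp"))
  expect_error(cd274_class(3L), "GISTIC")
})

test_that("neoantigen counting honors both boundaries", {
  pep <- data.frame(mutation = c("m1", "m2", "m3", "m3"),
                    ic50_nM = c(499, 500, 10, 800))
  expr <- data.frame(mutation = c("m1", "m2", "m3"),
                     read_count = c(1L, 100L, 0L))
  n <- count_neoantigens(pep, expr)
  expect_equal(as.integer(n), 1L)  # m1 only: ic50 < 500 and reads >= 1
  pep2 <- rbind(pep, data.frame(mutation = "m4", ic50_nM = 5))
  expect_message(n2 <- count_neoantigens(pep2, expr), "lack expression")
  expect_equal(attr(n2, "excluded"), "m4")
})

test_that("actionability classification picks the best OncoKB level and chemo call", {
  ok <- read_oncokb_snapshot()
  hrd_hi <- classify_hrd_status(20, 15, 10)
  hrd_lo <- classify_hrd_status(1, 1, 1)

  none <- classify_actionability(NULL, hrd_hi, ok)
  expect_true(none$chemo_responsive)
  expect_equal(none$oncokb_level, "none")

  alt <- data.frame(gene = c("BRCA1", "PIK3CA"),
                    alteration_type = c("mutation", "mutation"),
                    alteration = c("c.68_69del", "E545K"),
                    stringsAsFactors = FALSE)
  r <- classify_actionability(alt, hrd_lo, ok, cd274_cn = 6)
  expect_false(r$chemo_responsive)
  expect_equal(r$oncokb_level, "1")      # best among {1, 3b}
  expect_equal(r$cd274_class, "high_amp")

  unk <- data.frame(gene = "ZZZ9", alteration_type = "mutation",
                    alteration = "any", stringsAsFactors = FALSE)
  r2 <- classify_actionability(unk, hrd_lo, ok)
  expect_equal(r2$oncokb_level, "none")
  expect_equal(r2$unmatched, 1L)
})

test_that("planted HRD-high prevalence is recovered as the responsive fraction", {
  set.seed(24)
  brca <- rbinom(200, 1, 0.1) == 1
  score <- ifelse(runif(200) < 0.6, 50L, 10L)  # ~60% score-high
  status <- vapply(seq_len(200), function(i)
    classify_hrd_status(score[i], 0L, 0L, brca_flag = brca[i])$status,
    character(1))
  frac <- mean(status == "HRD-high")
  truth <- mean(score >= 42 | brca)
  expect_equal(frac, truth)
})

test_that("the packaged comparison count table loads and reproduces known contrasts", {
  path <- system.file("extdata", "cohort_counts_synthetic.tsv",
                      package = "mutscape")
  tab <- read.delim(path, comment.char = "#")
  aa <- list(n = 462, counts = setNames(tab$AA, tab$gene))
  chn <- list(n = 279, counts = setNames(tab$CHN, tab$gene))
  r <- compare_frequencies(aa, chn)
  expect_lt(r$p[r$gene == "TP53"], 1e-9)
  expect_true(r$flagged[r$gene == "PIK3CA"])
})
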