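make_call_sets <- function(records, callers = c("strelka", "muse",
                                                "vardict", "mutect")) {
  stats::setNames(lapply(callers, function(cl) records), callers)
}

test_that("integrate_callers merges identical calls and applies support threshold", {
  rec <- clean_snv(1)
  merged <- integrate_callers(make_call_sets(rec))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_callers, 4L)
  expect_setequal(strsplit(merged$callers, ",")[[1]],
                  c("strelka", "muse", "vardict", "mutect"))

  one <- list(strelka = clean_snv(1))
  expect_equal(nrow(integrate_callers(one, min_support = 2L)), 0L)
  expect_equal(nrow(integrate_callers(one, min_support = 1L)), 1L)
})

test_that("integrate_callers output equals the brute-force union for random call sets", {
  set.seed(7)
  for (rep in 1:10) {
    pool <- clean_snv(12)
    pool$pos <- 1:12
    sets <- lapply(1:3, function(i) {
      pool[sort(sample(12, sample(4:9, 1))), , drop = FALSE]
    })
    names(sets) <- c("strelka", "muse", "vardict")
    merged <- integrate_callers(sets)
    union_keys <- unique(unlist(lapply(sets, function(s)
      paste(s$sample_id, s$chrom, s$pos, s$ref, s$alt))))
    expect_equal(nrow(merged), length(union_keys))
  }
})

test_that("integrate_callers rejects conflicting reference alleles", {
  a <- clean_snv(1)
  b <- clean_snv(1); b$ref <- "G"; b$alt <- "A"
  expect_error(integrate_callers(list(strelka = a, muse = b)), "conflicting")
})

test_that("filter_snvs applies the four evidence criteria with accumulated reasons", {
  ok <- clean_snv(1)
  d <- filter_snvs(ok)
  expect_true(d$passed)
  expect_equal(d$reasons, "")

  # alt present in normal, tumor/normal contingency not significant
  # (Fisher two-sided p = 0.0734 >= 0.05, enumeration oracle)
  ne <- clean_snv(1)
  ne$t_alt <- 20L; ne$t_ref <- 80L; ne$n_alt <- 10L; ne$n_ref <- 90L
  ne$alt_fwd <- 10L; ne$alt_rev <- 10L
  expect_equal(fisher_oracle(20, 80, 10, 90), 0.07342759, tolerance = 1e-6)
  d <- filter_snvs(ne)
  expect_false(d$passed)
  expect_equal(d$reasons, "normal_evidence")

  # all alt reads on one strand with significant strand contingency
  # (Fisher p = 1.13e-4 < 0.05, enumeration oracle)
  sb <- clean_snv(1)
  sb$t_alt <- 15L; sb$t_ref <- 100L
  sb$alt_fwd <- 15L; sb$alt_rev <- 0L; sb$ref_fwd <- 50L; sb$ref_rev <- 50L
  expect_lt(fisher_oracle(15, 0, 50, 50), 0.05)
  d <- filter_snvs(sb)
  expect_false(d$passed)
  expect_equal(d$reasons, "strand_bias")

  # multiple failures accumulate, not short-circuit
  multi <- sb
  multi$alt_mq <- 5
  multi$site_bq <- 20
  d <- filter_snvs(multi)
  expect_setequal(strsplit(d$reasons, ",")[[1]],
                  c("strand_bias", "base_quality_drop", "poor_mapping"))
})

test_that("records with missing strand evidence are unevaluable, not silently passed", {
  r <- clean_snv(1)
  r$alt_fwd <- NA_real_
  d <- filter_snvs(r)
  expect_true(d$unevaluable)
  expect_true(is.na(d$passed))
})

test_that("filtering is idempotent on passed records", {
  set.seed(3)
  b <- generate_cohort(cohort_config(5, seed = 4), segment_level = FALSE)
  merged <- integrate_callers(b$caller_calls)
  snv <- merged[merged$variant_class == "SNV", ]
  d1 <- filter_snvs(snv)
  kept <- snv[!is.na(d1$passed) & d1$passed, ]
  d2 <- filter_snvs(kept)
  expect_true(all(d2$passed))
  expect_true(all(d2$reasons == ""))
})

test_that("filter_indels rejects homopolymer 1-bp events and keeps clean indels", {
  ins <- data.frame(sample_id = "S1", chrom = "chr1", pos = 10L,
                    ref = "-", alt = "A", variant_class = "insertion",
                    hp_len = 7L, t_alt = 20L, t_ref = 80L, n_alt = 0L,
                    n_ref = 100L, alt_mq = 60, stringsAsFactors = FALSE)
  d <- filter_indels(ins)
  expect_false(d$passed)
  expect_equal(d$reasons, "homopolymer")

  del5 <- data.frame(sample_id = "S1", chrom = "chr1", pos = 10L,
                     ref = "CATGA", alt = "-", variant_class = "deletion",
                     t_alt = 20L, t_ref = 80L, n_alt = 0L, n_ref = 100L,
                     alt_mq = 60, stringsAsFactors = FALSE)
  expect_true(filter_indels(del5)$passed)

  # mixed fixture with known labels
  labels <- c(rep(TRUE, 8), rep(FALSE, 12))
  hp <- c(sample(0:5, 8, replace = TRUE), sample(6:9, 6, replace = TRUE),
          rep(2L, 6))
  mq <- c(rep(60, 14), rep(5, 6))
  fx <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:20,
                   ref = "-", alt = "A", variant_class = "insertion",
                   hp_len = hp, t_alt = 20L, t_ref = 80L, n_alt = 0L,
                   n_ref = 100L, alt_mq = mq, stringsAsFactors = FALSE)
  expect_equal(filter_indels(fx)$passed, labels)
})

test_that("mutation burden uses the exome target size with a strict hypermutation boundary", {
  rec <- clean_snv(95)
  b <- mutation_burden(rec)
  expect_equal(b$snvs_per_mb, 95 / 73.499, tolerance = 1e-12)
  expect_false(b$hypermutated)

  # boundary: exactly 10 SNVs/Mb is not hypermutated under ">", is under ">="
  rec10 <- clean_snv(100)
  expect_false(mutation_burden(rec10, target_size_mb = 10)$hypermutated)
  expect_true(mutation_burden(rec10, target_size_mb = 10,
                              inclusive = TRUE)$hypermutated)
  expect_true(mutation_burden(clean_snv(101),
                              target_size_mb = 10)$hypermutated)

  z <- mutation_burden(clean_snv(1)[0, ], sample_ids = "S1")
  expect_equal(z$snvs_per_mb, 0)
  expect_false(z$hypermutated)
  expect_error(mutation_burden(rec, target_size_mb = 0), "positive")
})

test_that("gene_frequency counts each sample once per gene", {
  rec <- clean_snv(3)
  rec$gene <- "TP53"; rec$nonsilent <- TRUE
  gf <- gene_frequency(rec, n_samples = 462)
  expect_equal(gf$mutated_samples, 1L)

  many <- do.call(rbind, lapply(sprintf("S%02d", 1:10), function(s)
    clean_snv(1, sample_id = s)))
  many$gene <- "TP53"; many$nonsilent <- TRUE
  gf <- gene_frequency(many, n_samples = 462)
  expect_equal(gf$mutated_samples, 10L)
  expect_equal(gf$frequency, 10 / 462, tolerance = 1e-12)
  expect_equal(nrow(gene_frequency(many, 462, min_frequency = 0.02)), 1L)
  expect_error(gene_frequency(many, 0), "positive")
})

test_that("summarize_classes reports integer-rounded percentages", {
  rec <- clean_snv(10)
  s <- summarize_classes(rec)
  expect_equal(s$pct_snv, 100L)
  expect_equal(summarize_classes(rec[0, ])$total, 0L)
})
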