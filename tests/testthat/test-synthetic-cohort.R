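test_that("an empty cohort yields valid empty tables", {
  b <- generate_cohort(cohort_config(0))
  expect_equal(nrow(b$patients), 0L)
  expect_equal(nrow(b$truth), 0L)
  expect_equal(nrow(b$segments), 0L)
  expect_equal(nrow(b$context_matrix), 0L)
})

test_that("configuration validation catches bad inputs", {
  expect_error(cohort_config(-1), "non-negative")
  expect_error(cohort_config(5, signature_profiles = matrix(-1, 5, 5)),
               "non-negative")
  expect_error(cohort_config(5, artifact_rates = c(strand_bias = 1.2,
                                                   normal_contamination = 0,
                                                   low_mq = 0,
                                                   base_quality = 0)),
               "rates")
  expect_error(cohort_config(5, subtype_truth = c(1, 2)), "per patient")
  expect_error(generate_cohort(cohort_config(2),
                               catalog = load_sbs_catalog()[, 0]), "empty")
})

test_that("fixed seed gives identical bundles", {
  cfg <- cohort_config(8, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients, b$patients)
  expect_identical(a$segments, b$segments)
  expect_identical(a$caller_calls, b$caller_calls)
})

test_that("a single-signature tumor draws channel counts from that profile", {
  catal <- load_sbs_catalog()
  W <- matrix(0, 1, 5, dimnames = list(NULL, colnames(catal)))
  W[1, "SBS2"] <- 1
  cfg <- cohort_config(1, signature_profiles = W,
                       burden_meanlog = log(10000 / 73.499),
                       burden_sdlog = 0, seed = 32)
  b <- generate_cohort(cfg, mutation_level = FALSE, segment_level = FALSE)
  counts <- as.numeric(b$context_matrix[1, ])
  expect_equal(sum(counts), 10000)
  # chi-square goodness of fit against the generating profile
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = as.numeric(catal[, "SBS2"])))
  expect_gt(gof$p.value, 1e-3)
})

test_that("generated exposures are recovered by reference decomposition", {
  catal <- load_sbs_catalog()
  cfg <- cohort_config(40, burden_meanlog = log(800 / 73.499),
                       burden_sdlog = 0, seed = 33)
  b <- generate_cohort(cfg, mutation_level = FALSE, segment_level = FALSE)
  est <- decompose_to_reference(b$context_matrix, catal, drop_tol = 0)
  cs <- vapply(seq_len(nrow(est)), function(i)
    cosine_similarity(est[i, ], b$exposures_true[i, ]), numeric(1))
  expect_true(all(cs >= 0.95))
})

test_that("artifact injection respects rates and designed evidence", {
  b <- generate_cohort(cohort_config(4, seed = 34), segment_level = FALSE)
  truth <- b$truth

  # rates all zero: call sets are subsets of truth (dropout only)
  clean <- inject_artifacts(truth, rates = c(strand_bias = 0,
                                             normal_contamination = 0,
                                             low_mq = 0, base_quality = 0),
                            dropout = 0.1, seed = 1)
  for (cl in clean) {
    expect_true(all(is.na(cl$artifact)))
    expect_lte(nrow(cl), nrow(truth))
  }

  # strand-bias rate 1: every artifact has alt reads on a single strand
  sb <- inject_artifacts(truth, rates = c(strand_bias = 1,
                                          normal_contamination = 0,
                                          low_mq = 0, base_quality = 0),
                         dropout = 0, seed = 2)
  art <- do.call(rbind, sb)
  art <- art[!is.na(art$artifact), ]
  expect_true(all(art$alt_rev == 0 | art$alt_fwd == 0))

  # binomial oracle on the artifact count at rate 0.1
  n <- nrow(truth)
  a10 <- inject_artifacts(truth, rates = c(strand_bias = 0.1,
                                           normal_contamination = 0,
                                           low_mq = 0, base_quality = 0),
                          dropout = 0, seed = 3)
  uniq <- unique(do.call(rbind, a10)[, c("pos", "artifact")])
  k <- sum(!is.na(uniq$artifact))
  ci <- qbinom(c(0.0005, 0.9995), n, 0.1)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})

test_that("labeled artifacts are rejected with their designed reason", {
  b <- generate_cohort(cohort_config(6, seed = 35), segment_level = FALSE)
  merged <- integrate_callers(b$caller_calls)
  snv <- merged[merged$variant_class == "SNV", ]
  dec <- filter_snvs(snv)
  is_art <- !is.na(snv$artifact)
  expect_gte(mean(!dec$passed[is_art]), 0.95)
  expect_true(all(dec$passed[!is_art]))
  map <- c(strand_bias = "strand_bias",
           normal_contamination = "normal_evidence",
           low_mq = "poor_mapping", base_quality = "base_quality_drop")
  for (kind in names(map)) {
    idx <- which(is_art & snv$artifact == kind)
    if (length(idx)) {
      expect_gte(mean(grepl(map[kind], dec$reasons[idx])), 0.95)
    }
  }
})

test_that("simulate_tas_reads follows the binomial model", {
  expect_error(simulate_tas_reads(0.5, -5), "positive")
  expect_error(simulate_tas_reads(1.5, 100), "vaf")
  z <- simulate_tas_reads(0, 1000, error_rate = 0, seed = 1)
  expect_equal(z$alt_t, 0L); expect_equal(z$alt_c, 0L)
  r <- simulate_tas_reads(0.5, 10000, seed = 2)
  expect_gt(r$alt_t / 10000, 0.48); expect_lt(r$alt_t / 10000, 0.52)
  expect_identical(simulate_tas_reads(0.3, 500, seed = 9),
                   simulate_tas_reads(0.3, 500, seed = 9))
})

test_that("planted gene frequencies are recovered exactly", {
  gf <- c(TP53 = 0.9, PIK3CA = 0.25, NOTCH1 = 0.1)
  cfg <- cohort_config(40, gene_frequencies = gf, seed = 36)
  b <- generate_cohort(cfg, segment_level = FALSE)
  tab <- gene_frequency(b$truth, n_samples = 40)
  expect_equal(tab$mutated_samples[match(names(gf), tab$gene)],
               as.integer(round(gf * 40)))
})

test_that("survival truth reflects the planted subtype hazards", {
  cfg <- cohort_config(2000, hazard_ratios = c("1" = 1, "2" = 1, "3" = 8,
                                               "4" = 1), seed = 37)
  b <- generate_cohort(cfg, mutation_level = FALSE, segment_level = FALSE)
  p <- b$patients
  expect_true(all(p$time > 0))
  # far higher event rate in the high-hazard subtype
  e1 <- mean(p$event[p$subtype_truth == 1])
  e3 <- mean(p$event[p$subtype_truth == 3])
  expect_gt(e3, e1 + 0.2)
})

test_that("cohort bundles round-trip through the on-disk layout", {
  b <- generate_cohort(cohort_config(3, seed = 38), segment_level = FALSE)
  d <- tempfile("cohort")
  write_cohort(b, d)
  maf <- read_maf(file.path(d, "truth_mutations.tsv"))
  expect_equal(nrow(maf), nrow(b$truth))
  clin <- read.csv(file.path(d, "clinical.csv"))
  expect_equal(clin$sample_id, b$patients$sample_id)
  unlink(d, recursive = TRUE)
})
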