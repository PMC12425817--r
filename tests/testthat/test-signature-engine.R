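test_that("sbs_channel collapses purine substitutions to the pyrimidine strand", {
  expect_equal(sbs_channel("C", "T", "ACG"), "A[C>T]G")
  # G>A at C_T context is the reverse complement of A[C>T]G
  expect_equal(sbs_channel("G", "A", "CGT"), "A[C>T]G")
  expect_true(is.na(sbs_channel("C", "T", "ANG")))
  expect_true(is.na(sbs_channel("C", "T", "AAG")))  # context mismatch
})

test_that("build_sbs_matrix conserves counts and excludes ambiguous contexts", {
  set.seed(5)
  b <- generate_cohort(cohort_config(6, seed = 5), segment_level = FALSE)
  snv <- b$truth[b$truth$variant_class == "SNV", ]
  snv$channel <- NULL
  m <- build_sbs_matrix(snv)
  expect_equal(sum(m), nrow(snv))
  expect_equal(unname(rowSums(m)),
               as.integer(table(snv$sample_id)[rownames(m)]))
  expect_identical(colnames(m), sbs96_channels())

  snv$context[1] <- "NNN"
  m2 <- build_sbs_matrix(snv)
  expect_equal(attr(m2, "excluded"), 1L)
  expect_equal(sum(m2), nrow(snv) - 1L)
})

test_that("classify_indel follows the ID83 rules", {
  # 1-bp T deletion inside a TTTTT run: 4 flanking copies
  expect_equal(classify_indel("T", "-", "GGGTT", "TTGGG"), "1:Del:T:4")
  # 1-bp C insertion with no existing run
  expect_equal(classify_indel("-", "C", "GGGGA", "AGGGG"), "1:Ins:C:0")
  # 4-bp deletion with 2-bp flanking microhomology, not in a repeat
  expect_equal(classify_indel("CATG", "-", strrep("A", 25),
                              paste0("CA", strrep("G", 25))), "4:Del:M:2")
  # 1-bp A deletion is represented on the pyrimidine strand as T
  expect_equal(classify_indel("A", "-", "GGGGG", "GGGGG"), "1:Del:T:0")
  # deletions longer than 5 bp fall in the 5+ class
  expect_equal(classify_indel("CATGACA", "-", strrep("G", 30),
                              strrep("T", 30)), "5:Del:R:0")
  # insufficient flank is unclassifiable
  expect_true(is.na(classify_indel("T", "-", "TT", "TT")))
})

test_that("every ID83 channel round-trips through its constructed example", {
  chans <- id83_channels()
  got <- vapply(chans, function(ch) {
    ex <- indel_from_channel(ch)
    classify_indel(ex$ref, ex$alt, ex$flank5, ex$flank3)
  }, character(1))
  expect_equal(unname(got), chans)
})

test_that("KL objective is non-increasing across multiplicative updates", {
  set.seed(8)
  V <- matrix(rpois(30 * 8, 5), 30, 8)
  fit <- mutscape:::nmf_kl(V, 3, max_iter = 300)
  expect_true(all(diff(fit$trace) <= 1e-8 * pmax(1, abs(fit$trace[-1]))))
})

test_that("rank-1 KL-NMF recovers the normalized channel sum", {
  set.seed(9)
  V <- matrix(rpois(20 * 10, 8), 20, 10)
  fit <- mutscape:::nmf_kl(V, 1, max_iter = 2000)
  expect_gt(cosine_similarity(fit$W[, 1], rowSums(V)), 1 - 1e-8)
})

test_that("extract_denovo recovers well-separated signatures and selects their number", {
  catal <- load_sbs_catalog()[, c("SBS1", "SBS3", "SBS13")]
  set.seed(10)
  mix <- matrix(rexp(3 * 30), 3, 30)
  mix <- sweep(mix, 2, colSums(mix), "/")
  lam <- 400 * t(catal %*% mix)
  X <- matrix(rpois(length(lam), as.numeric(lam)), nrow(lam),
              dimnames = list(paste0("s", 1:30), rownames(catal)))
  res <- extract_denovo(X, k_range = 1:4, n_replicates = 4, seed = 2,
                        max_iter = 800)
  expect_equal(res$selected_k, 3L)
  m <- res$model
  match_cos <- apply(m$signatures, 2, function(s)
    max(apply(catal, 2, function(r) cosine_similarity(s, r))))
  expect_true(all(match_cos >= 0.9))
  # reconstruction conserves per-sample totals within 1%
  recon <- m$exposures %*% t(m$signatures)
  expect_true(all(abs(rowSums(recon) - rowSums(X)) / rowSums(X) < 0.01))
  # column-stochastic signatures
  expect_equal(unname(colSums(m$signatures)), rep(1, 3), tolerance = 1e-8)
})

test_that("extract_denovo is deterministic under a fixed seed and validates k_range", {
  set.seed(1)
  X <- matrix(rpois(96 * 10, 4), 10, 96,
              dimnames = list(paste0("s", 1:10), sbs96_channels()))
  a <- extract_denovo(X, k_range = 2, n_replicates = 3, seed = 7,
                      max_iter = 200)
  b <- extract_denovo(X, k_range = 2, n_replicates = 3, seed = 7,
                      max_iter = 200)
  expect_identical(a$model$signatures, b$model$signatures)
  expect_error(extract_denovo(X, k_range = 0:2), "k_range")
})

test_that("decompose_to_reference solves noiseless mixtures exactly", {
  catal <- load_sbs_catalog()
  v <- 1000 * (0.6 * catal[, "SBS1"] + 0.4 * catal[, "SBS3"])
  e <- decompose_to_reference(as.numeric(v), catal)
  expect_equal(unname(e[1, c("SBS1", "SBS3")]), c(600, 400), tolerance = 1e-6)
  expect_equal(unname(e[1, c("SBS2", "SBS5", "SBS13")]), rep(0, 3))

  # zero vector: all-zero exposures
  z <- decompose_to_reference(rep(0, 96), catal)
  expect_true(all(z == 0))

  # single-signature catalog: closed-form 1-D NNLS projection
  s <- catal[, "SBS2", drop = FALSE]
  set.seed(4)
  v2 <- rpois(96, 10)
  e2 <- decompose_to_reference(v2, s)
  expect_equal(unname(e2[1, 1]), max(0, sum(v2 * s) / sum(s^2)),
               tolerance = 1e-8)
  expect_error(decompose_to_reference(rep(1, 50), catal), "channel")
})

test_that("backward elimination finds the true active set when contributions are resolvable", {
  catal <- load_sbs_catalog()
  # equal-weight mixtures in which removing any active signature costs
  # more than the 0.01 cosine tolerance
  sets <- list(c("SBS1", "SBS2", "SBS5"), c("SBS2", "SBS3", "SBS5"),
               c("SBS1", "SBS13"), c("SBS2", "SBS13"),
               c("SBS1", "SBS2", "SBS13"))
  for (active in sets) {
    k <- length(active)
    v <- 2000 * as.numeric(catal[, active, drop = FALSE] %*% rep(1 / k, k))
    e <- decompose_to_reference(v, catal)
    got <- colnames(catal)[e[1, ] > 1]
    expect_setequal(got, active)
    # agrees with the brute-force best subset of that size
    expect_setequal(best_subset_cosine(v, catal, k), sort(active))
  }
})

test_that("backward elimination drops a signature whose removal is within tolerance", {
  catal <- load_sbs_catalog()
  # 0.7 SBS1 + 0.3 SBS3: removing SBS3 costs ~0.007 cosine, below the
  # 0.01 sparsity tolerance, so the sparse fit attributes all mass to SBS1
  v <- 2000 * as.numeric(catal %*% c(0.7, 0, 0.3, 0, 0))
  e <- decompose_to_reference(v, catal, drop_tol = 0.01)
  expect_equal(unname(e[1, "SBS3"]), 0)
  # at drop_tol = 0 the full NNLS solution is returned unchanged
  e0 <- decompose_to_reference(v, catal, drop_tol = 0)
  expect_equal(unname(e0[1, c("SBS1", "SBS3")]), c(1400, 600),
               tolerance = 1e-6)
})

test_that("exposure correlations report Pearson r with two-sided p", {
  set.seed(6)
  ex <- data.frame(SBS1 = rlnorm(60), SBS3 = rlnorm(60))
  cov <- data.frame(self = ex$SBS1, flat = rep(1, 60))
  tab <- exposure_correlations(ex, cov)
  r_self <- tab$r[tab$signature == "SBS1" & tab$covariate == "self"]
  expect_equal(r_self, 1, tolerance = 1e-12)
  expect_true(is.na(tab$r[tab$covariate == "flat"][1]))

  # planted correlation 0.6 at n = 400 recovered within sampling error
  set.seed(21)
  x <- rnorm(400)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(400)
  tab2 <- exposure_correlations(data.frame(sig = x), data.frame(cov = y))
  expect_lt(abs(tab2$r - 0.6), 0.08)
  expect_lt(tab2$p, 1e-10)
})
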