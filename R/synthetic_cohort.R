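#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: per-tumor mutation catalogs drawn multinomially from
#' known signature mixtures, a log-normal burden distribution, caller
#' call sets with injected artifacts that each violate exactly one
#' filter criterion, allele-specific copy-number segments with planted
#' LOH/TAI/LST events coupled to SBS3 activity, and survival times whose
#' hazard depends on the SBS subtype truth.
#'
#' @param n_patients Cohort size.
#' @param signature_profiles Optional n x k matrix of per-tumor mixing
#'   weights over the reference catalog (rows renormalized to sum 1).
#'   When NULL and the catalog carries the SBS1/2/3/5/13 signatures,
#'   weights are drawn from a Gaussian-copula model calibrated to the
#'   correlation structure reported for TNBC: the HRD (SBS3) share is
#'   strongly coupled to total burden (HRD-dominated tumors mutate more),
#'   producing a moderate negative SBS3-SBS5 activity correlation
#'   (about -0.3) and a positive SBS1-SBS5 correlation (about 0.45),
#'   with APOBEC (SBS2/SBS13) activity present in about 35\% of tumors
#'   and strongly internally correlated. Otherwise a flat Dirichlet is
#'   used.
#' @param burden_meanlog,burden_sdlog Log-normal parameters of SNVs/Mb
#'   (defaults reproduce a median near 1.29 SNVs/Mb with a long tail).
#' @param target_size_mb Sequenced target size used to convert burden to
#'   mutation counts.
#' @param indel_fraction Expected indels per SNV (cohort-level indel
#'   share around 7\%).
#' @param subtype_truth Optional integer vector (values 1-4) forcing the
#'   subtype truth instead of deriving it from the drawn exposures.
#' @param hazard_ratios Per-subtype multiplicative hazards (names "1"-"4");
#'   subtype 1 is the reference, subtype 3 carries the elevated
#'   mortality, subtypes 2/4 sit in between.
#' @param baseline_hazard Exponential baseline hazard per month.
#' @param censor_max Administrative censoring horizon (months, uniform).
#' @param artifact_rates Named probabilities (per truth mutation) of
#'   injecting an artifact of each type: \code{strand_bias},
#'   \code{normal_contamination}, \code{low_mq}, \code{base_quality}.
#' @param caller_dropout Probability that a caller misses a true variant.
#' @param gene_frequencies Optional named vector of per-gene mutation
#'   probabilities; \code{round(freq * n)} samples are planted with one
#'   nonsilent mutation in that gene (exact recovery).
#' @param brca_rate Probability of a pathogenic BRCA1/2 flag.
#' @param hrd_mean,hrd_sd,hrd_sbs3_r Parameters of the planted HRD score:
#'   normal with the given mean/sd, correlated with SBS3 exposure at
#'   \code{hrd_sbs3_r}.
#' @param seed Integer seed; a fixed seed yields identical bundles.
#' @return Validated configuration list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients,
                          signature_profiles = NULL,
                          burden_meanlog = log(1.29),
                          burden_sdlog = 0.9,
                          target_size_mb = 73.499,
                          indel_fraction = 0.075,
                          subtype_truth = NULL,
                          hazard_ratios = c("1" = 1, "2" = 1.5,
                                            "3" = 2.6, "4" = 1.5),
                          baseline_hazard = 0.008,
                          censor_max = 120,
                          artifact_rates = c(strand_bias = 0.02,
                                             normal_contamination = 0.02,
                                             low_mq = 0.02,
                                             base_quality = 0.02),
                          caller_dropout = 0.05,
                          gene_frequencies = NULL,
                          brca_rate = 0.10,
                          hrd_mean = 47, hrd_sd = 15, hrd_sbs3_r = 0.62,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 0 || n_patients != round(n_patients)) {
    stop("n_patients must be a non-negative integer")
  }
  if (!is.null(signature_profiles)) {
    signature_profiles <- as.matrix(signature_profiles)
    if (any(signature_profiles < 0)) stop("signature weights must be non-negative")
    rs <- rowSums(signature_profiles)
    if (any(rs <= 0)) stop("signature weights must have positive row sums")
    signature_profiles <- sweep(signature_profiles, 1L, rs, "/")
  }
  rates <- c(artifact_rates, caller_dropout = caller_dropout)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (!is.null(subtype_truth) &&
      (length(subtype_truth) != n_patients ||
         !all(subtype_truth %in% 1:4))) {
    stop("subtype_truth must give one value in 1..4 per patient")
  }
  if (abs(hrd_sbs3_r) > 1) stop("hrd_sbs3_r must lie in [-1, 1]")
  structure(list(
    n_patients = as.integer(n_patients),
    signature_profiles = signature_profiles,
    burden_meanlog = burden_meanlog, burden_sdlog = burden_sdlog,
    target_size_mb = target_size_mb, indel_fraction = indel_fraction,
    subtype_truth = subtype_truth, hazard_ratios = hazard_ratios,
    baseline_hazard = baseline_hazard, censor_max = censor_max,
    artifact_rates = artifact_rates, caller_dropout = caller_dropout,
    gene_frequencies = gene_frequencies, brca_rate = brca_rate,
    hrd_mean = hrd_mean, hrd_sd = hrd_sd, hrd_sbs3_r = hrd_sbs3_r,
    seed = as.integer(seed)), class = "cohort_config")
}

# default per-tumor mixing weights: HRD share coupled to the burden
# z-score (rho = 0.95) through a Beta(0.8, 0.8) marginal; aging split
# between SBS1/SBS5; APOBEC present in 35% of tumors. Calibrated to the
# activity correlations and subtype proportions reported for TNBC.
default_profiles <- function(n, z_n) {
  z3 <- 0.95 * z_n + sqrt(1 - 0.95^2) * stats::rnorm(n)
  p3 <- stats::qbeta(stats::pnorm(z3), 0.8, 0.8)
  ap_on <- stats::runif(n) < 0.35
  pap <- ifelse(ap_on, stats::qbeta(stats::runif(n), 1.5, 10), 0) * (1 - p3)
  aging <- 1 - p3 - pap
  f1 <- stats::rbeta(n, 5, 7)
  s2 <- stats::rbeta(n, 8, 8)
  cbind(SBS1 = aging * f1, SBS2 = pap * s2, SBS3 = p3,
        SBS5 = aging * (1 - f1), SBS13 = pap * (1 - s2))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  sweep(g, 1L, rowSums(g), "/")
}

#' Generate a synthetic tumor cohort with known ground truth
#'
#' @param config A [cohort_config()].
#' @param catalog SBS reference catalog (channels x signatures).
#' @param id_catalog ID83 reference catalog for indel channels.
#' @param annotation Genome annotation for segment planting.
#' @param mutation_level Materialize per-mutation truth records and
#'   caller call sets (set FALSE for large simulation studies that only
#'   need context matrices and clinical/survival truth).
#' @param segment_level Materialize allele-specific segments realizing
#'   the planted scar counts (set FALSE to skip; the planted component
#'   counts remain available in \code{patients}).
#' @return List of class \code{cohort_bundle}: \code{patients} (clinical,
#'   survival, HRD truth, subtype truth), \code{context_matrix} (samples
#'   x 96 counts), \code{exposures_true} (samples x signatures, counts),
#'   \code{truth} (mutation records), \code{caller_calls} (per-caller
#'   call sets with labeled artifacts), \code{segments}, \code{annotation},
#'   \code{expression}, \code{tas_reads}, \code{config}.
#' @export
generate_cohort <- function(config,
                            catalog = load_sbs_catalog(),
                            id_catalog = load_id_catalog(),
                            annotation = toy_genome(24L),
                            mutation_level = TRUE, segment_level = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (ncol(catalog) == 0) stop("reference catalog is empty")
  set.seed(config$seed)
  n <- config$n_patients
  sig_names <- colnames(catalog)
  if (n == 0L) {
    return(structure(list(
      patients = empty_patients(), context_matrix =
        matrix(0L, 0, nrow(catalog), dimnames = list(NULL, rownames(catalog))),
      exposures_true = matrix(0, 0, ncol(catalog),
                              dimnames = list(NULL, sig_names)),
      truth = empty_truth(), caller_calls = NULL,
      segments = empty_segments(), annotation = annotation,
      expression = NULL, tas_reads = NULL, config = config),
      class = "cohort_bundle"))
  }
  ids <- sprintf("S%04d", seq_len(n))

  z_n <- stats::rnorm(n)
  burden <- exp(config$burden_meanlog + config$burden_sdlog * z_n)
  n_snv <- pmax(1L, as.integer(round(burden * config$target_size_mb)))

  W <- config$signature_profiles
  if (is.null(W)) {
    W <- if (all(c("SBS1", "SBS2", "SBS3", "SBS5", "SBS13") %in% sig_names)) {
      default_profiles(n, z_n)[, sig_names, drop = FALSE]
    } else {
      w <- rdirichlet(n, rep(1, length(sig_names)))
      colnames(w) <- sig_names
      w
    }
  }
  if (is.null(colnames(W))) colnames(W) <- sig_names
  rownames(W) <- ids
  n_indel <- stats::rbinom(n, n_snv, config$indel_fraction)

  channels <- rownames(catalog)
  ctx <- matrix(0L, n, length(channels), dimnames = list(ids, channels))
  probs <- catalog %*% t(W)           # channels x samples
  for (i in seq_len(n)) {
    ctx[i, ] <- as.integer(stats::rmultinom(1L, n_snv[i], probs[, i]))
  }
  exposures_true <- W * n_snv

  # subtype truth from the noiseless exposures (or forced)
  subtype <- config$subtype_truth
  if (is.null(subtype)) {
    subtype <- if (n >= 3L &&
                   all(c("SBS1", "SBS5", "SBS3") %in% sig_names)) {
      assign_sbs_subtype(as.data.frame(exposures_true))$subtype
    } else rep(NA_integer_, n)
  }

  # survival: exponential hazard scaled by subtype truth
  hr <- config$hazard_ratios[as.character(subtype)]
  hr[is.na(hr)] <- 1
  t_event <- stats::rexp(n, rate = config$baseline_hazard * hr)
  t_cens <- stats::runif(n, 0, config$censor_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # clinical covariates, age/BMI coupled to aging activity
  aging_z <- as.numeric(scale(rank(exposures_true[, "SBS1"] +
                                     exposures_true[, "SBS5"])))
  age <- round(53 + 11 * (0.5 * aging_z + sqrt(1 - 0.25) * stats::rnorm(n)))
  bmi <- round(30 + 6 * (0.3 * aging_z + sqrt(1 - 0.09) * stats::rnorm(n)), 1)
  stage <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
  study <- sample(c("A", "B", "C"), n, replace = TRUE)
  brca <- stats::rbinom(n, 1L, config$brca_rate) == 1L

  # planted HRD scar counts, correlated with SBS3 exposure
  sbs3 <- if ("SBS3" %in% sig_names) exposures_true[, "SBS3"] else rep(0, n)
  z3 <- if (n >= 2 && isTRUE(stats::sd(sbs3) > 0)) as.numeric(scale(sbs3))
        else rep(0, n)
  r <- config$hrd_sbs3_r
  score <- pmax(0L, as.integer(round(
    config$hrd_mean + config$hrd_sd *
      (r * z3 + sqrt(1 - r^2) * stats::rnorm(n)))))
  capacity <- scar_capacity(annotation)
  # clamp extreme draws to what the simulated genome can host
  score_cap <- floor(min(capacity$total_budget_mb / 52, 3 * capacity$tai))
  score <- pmin(score, score_cap)
  comp <- vapply(score, function(s)
    as.integer(stats::rmultinom(1L, s, c(0.4, 0.3, 0.3))), integer(3))
  loh_n <- comp[1, ]
  tai_n <- pmin(comp[2, ], capacity$tai)
  lst_n <- comp[3, ]

  patients <- data.frame(
    sample_id = ids, age = age, bmi = bmi, stage = stage, study = study,
    brca_pathogenic = brca, time = time, event = event,
    subtype_truth = subtype,
    loh_truth = loh_n, tai_truth = tai_n, lst_truth = lst_n,
    hrd_score_truth = loh_n + tai_n + lst_n,
    snvs_per_mb_truth = n_snv / config$target_size_mb,
    stringsAsFactors = FALSE)

  segments <- if (segment_level) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      plant_scar_segments(ids[i], loh_n[i], tai_n[i], lst_n[i], annotation)
    }))
  } else empty_segments()

  truth <- NULL; caller_calls <- NULL; expression <- NULL; tas <- NULL
  if (mutation_level) {
    truth <- materialize_mutations(ids, ctx, n_indel, id_catalog, annotation,
                                   config$gene_frequencies)
    caller_calls <- inject_artifacts(truth, rates = config$artifact_rates,
                                     dropout = config$caller_dropout)
    genes <- unique(stats::na.omit(truth$gene))
    if (length(genes)) {
      expression <- matrix(stats::rnbinom(length(genes) * n, mu = 50, size = 2),
                           length(genes), n, dimnames = list(genes, ids))
    }
    tp53 <- truth[!is.na(truth$gene) & truth$gene == "TP53", , drop = FALSE]
    if (nrow(tp53)) {
      vaf <- tp53$t_alt / (tp53$t_alt + tp53$t_ref)
      tas <- cbind(tp53[, c("sample_id", "chrom", "pos", "ref", "alt")],
                   simulate_tas_reads(vaf, depth = 2000L))
    }
  }
  structure(list(patients = patients, context_matrix = ctx,
                 exposures_true = exposures_true, truth = truth,
                 caller_calls = caller_calls, segments = segments,
                 annotation = annotation, expression = expression,
                 tas_reads = tas, config = config),
            class = "cohort_bundle")
}

empty_patients <- function() {
  data.frame(sample_id = character(0), age = numeric(0), bmi = numeric(0),
             stage = integer(0), study = character(0),
             brca_pathogenic = logical(0), time = numeric(0),
             event = integer(0), subtype_truth = integer(0),
             loh_truth = integer(0), tai_truth = integer(0),
             lst_truth = integer(0), hrd_score_truth = integer(0),
             snvs_per_mb_truth = numeric(0), stringsAsFactors = FALSE)
}
empty_truth <- function() {
  mutation_records(data.frame(sample_id = character(0), chrom = character(0),
                              pos = integer(0), ref = character(0),
                              alt = character(0), variant_class = character(0),
                              stringsAsFactors = FALSE))
}
empty_segments <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), total_cn = integer(0),
             minor_cn = integer(0), stringsAsFactors = FALSE)
}

# expand per-sample channel counts into mutation records with clean evidence
materialize_mutations <- function(ids, ctx, n_indel, id_catalog, annotation,
                                  gene_frequencies) {
  channels <- colnames(ctx)
  rows <- list()
  id_channels <- rownames(id_catalog)
  id_mix <- rowMeans(id_catalog)
  for (i in seq_along(ids)) {
    chan <- rep(channels, ctx[i, ])
    m <- length(chan)
    # unique positions per sample so no two events share a locus
    pos_all <- sample.int(1e6L, m + n_indel[i])
    if (m) {
      ref <- substr(chan, 3, 3)
      alt <- substr(chan, 5, 5)
      context <- paste0(substr(chan, 1, 1), ref, substr(chan, 7, 7))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i],
        chrom = sample(annotation$chrom, m, replace = TRUE),
        pos = pos_all[seq_len(m)],
        ref = ref, alt = alt, variant_class = "SNV",
        context = context, channel = chan, stringsAsFactors = FALSE)
    }
    if (n_indel[i] > 0) {
      ich <- sample(id_channels, n_indel[i], replace = TRUE, prob = id_mix)
      ex <- do.call(rbind, lapply(ich, indel_from_channel))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = ids[i],
        chrom = sample(annotation$chrom, n_indel[i], replace = TRUE),
        pos = pos_all[m + seq_len(n_indel[i])],
        ref = ex$ref, alt = ex$alt, variant_class = ex$variant_class,
        context = NA_character_, channel = ich,
        flank5 = ex$flank5, flank3 = ex$flank3, hp_len = ex$hp_len,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    for (cn in c("flank5", "flank3")) if (!cn %in% names(r)) r[[cn]] <- NA_character_
    if (!"hp_len" %in% names(r)) r$hp_len <- NA_real_
    r
  }))
  m <- nrow(df)
  depth <- pmax(30L, as.integer(round(stats::rnorm(m, 154, 40))))
  vaf <- stats::runif(m, 0.15, 0.6)
  df$t_alt <- pmax(4L, stats::rbinom(m, depth, vaf))
  df$t_ref <- depth - df$t_alt
  ndepth <- pmax(30L, as.integer(round(stats::rnorm(m, 127, 35))))
  df$n_alt <- 0L
  df$n_ref <- ndepth
  df$alt_fwd <- stats::rbinom(m, df$t_alt, 0.5)
  # guard against an all-one-strand draw looking like designed strand bias
  flip <- df$t_alt >= 2 & (df$alt_fwd == 0 | df$alt_fwd == df$t_alt)
  df$alt_fwd[flip] <- df$t_alt[flip] %/% 2L
  df$alt_rev <- df$t_alt - df$alt_fwd
  df$ref_fwd <- stats::rbinom(m, df$t_ref, 0.5)
  df$ref_rev <- df$t_ref - df$ref_fwd
  df$site_bq <- 35; df$flank_bq <- 35; df$alt_mq <- 60
  df$gene <- NA_character_
  df$nonsilent <- FALSE
  df$artifact <- NA_character_

  # plant exact per-gene nonsilent frequencies
  if (!is.null(gene_frequencies)) {
    n <- length(ids)
    for (g in names(gene_frequencies)) {
      k <- round(gene_frequencies[[g]] * n)
      if (k == 0) next
      chosen <- sample(ids, k)
      for (s in chosen) {
        cand <- which(df$sample_id == s & is.na(df$gene))
        if (!length(cand)) {
          extra <- df[df$sample_id == s, , drop = FALSE][1, ]
          extra$gene <- NA_character_
          df <- rbind(df, extra)
          cand <- nrow(df)
        }
        j <- cand[1]
        df$gene[j] <- g
        df$nonsilent[j] <- TRUE
      }
    }
  }
  free <- is.na(df$gene)
  df$gene[free] <- sprintf("PSG%04d", sample.int(3000L, sum(free),
                                                 replace = TRUE))
  df$nonsilent[free] <- stats::runif(sum(free)) < 0.75
  rownames(df) <- NULL
  mutation_records(df)
}

#' Inject per-caller call sets with labeled artifacts
#'
#' Each of four pseudo-callers (strelka, muse, vardict, mutect) reports
#' every truth mutation minus independent dropout. Artifacts are added at
#' the given per-type rates; each artifact carries evidence engineered to
#' violate exactly one filter criterion and is labeled with its intended
#' rejection reason in the \code{artifact} column.
#'
#' @param truth Truth mutation table (clean evidence).
#' @param rates Named artifact probabilities per truth mutation:
#'   \code{strand_bias}, \code{normal_contamination}, \code{low_mq},
#'   \code{base_quality}.
#' @param dropout Per-caller probability of missing a true variant.
#' @param seed Optional seed (the cohort generator seeds globally).
#' @return Named list of four mutation tables.
#' @export
inject_artifacts <- function(truth,
                             rates = c(strand_bias = 0.02,
                                       normal_contamination = 0.02,
                                       low_mq = 0.02, base_quality = 0.02),
                             dropout = 0.05, seed = NULL) {
  if (any(rates < 0 | rates > 1) || dropout < 0 || dropout > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  callers <- c("strelka", "muse", "vardict", "mutect")
  m <- nrow(truth)
  artifacts <- list()
  mk_artifact <- function(kind, k) {
    if (k == 0L) return(NULL)
    base <- truth[sample.int(m, k, replace = TRUE), , drop = FALSE]
    base$pos <- base$pos + sample.int(5000L, k, replace = TRUE) + 1e6L
    base$variant_class <- "SNV"
    base$ref <- "C"; base$alt <- "T"; base$context <- "ACA"
    base$channel <- "A[C>T]A"
    base$gene <- NA_character_; base$nonsilent <- FALSE
    base$site_bq <- 35; base$flank_bq <- 35; base$alt_mq <- 60
    base$n_alt <- 0L; base$n_ref <- 120L
    base$t_alt <- 15L; base$t_ref <- 85L
    base$alt_fwd <- 8L; base$alt_rev <- 7L
    base$ref_fwd <- 43L; base$ref_rev <- 42L
    if (kind == "strand_bias") {
      base$alt_fwd <- base$t_alt; base$alt_rev <- 0L
      base$ref_fwd <- 43L; base$ref_rev <- 42L
    } else if (kind == "normal_contamination") {
      base$t_alt <- 10L; base$t_ref <- 90L
      base$n_alt <- 8L; base$n_ref <- 92L
      base$alt_fwd <- 5L; base$alt_rev <- 5L
    } else if (kind == "low_mq") {
      base$alt_mq <- 10
    } else if (kind == "base_quality") {
      base$site_bq <- 20; base$flank_bq <- 35
    }
    base$artifact <- kind
    base
  }
  kinds <- c(strand_bias = "strand_bias",
             normal_contamination = "normal_contamination",
             low_mq = "low_mq", base_quality = "base_quality")
  for (kind in names(kinds)) {
    k <- if (m > 0 && !is.na(rates[kind])) stats::rbinom(1L, m, rates[kind]) else 0L
    artifacts[[kind]] <- mk_artifact(kind, k)
  }
  art <- do.call(rbind, artifacts[!vapply(artifacts, is.null, logical(1))])
  membership <- NULL
  if (!is.null(art) && nrow(art)) {
    # every artifact appears in at least one caller
    membership <- matrix(stats::runif(nrow(art) * length(callers)) < 0.7,
                         nrow(art), length(callers))
    none <- rowSums(membership) == 0
    if (any(none)) {
      membership[cbind(which(none),
                       sample.int(length(callers), sum(none),
                                  replace = TRUE))] <- TRUE
    }
  }
  out <- list()
  for (ci in seq_along(callers)) {
    keep <- if (m > 0) stats::runif(m) >= dropout else logical(0)
    calls <- truth[keep, , drop = FALSE]
    if (!is.null(membership)) {
      calls <- rbind(calls, art[membership[, ci], , drop = FALSE])
    }
    rownames(calls) <- NULL
    out[[callers[ci]]] <- calls
  }
  out
}

#' Simulate subtype labels under a planted logistic age/BMI model
#'
#' Draws age and BMI and assigns subtype 1 versus subtype 3 from a
#' logistic model with the given log-odds coefficients; used to verify
#' that [subtype_odds()] recovers planted effects.
#'
#' @param n Number of patients.
#' @param beta_age Log-odds of subtype 1 per year of age (the default
#'   -0.115/year corresponds to a 68\% decrease per 10 years).
#' @param beta_bmi Log-odds per kg/m2 (default: 31\% decrease per
#'   5 kg/m2).
#' @param intercept Log-odds at the age/BMI means.
#' @param seed Optional seed.
#' @return Data frame \code{subtype} (1 or 3), \code{age}, \code{bmi}.
#' @export
simulate_subtype_labels <- function(n, beta_age = -0.115,
                                    beta_bmi = log(1 - 0.31) / 5,
                                    intercept = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age <- stats::rnorm(n, 53, 11)
  bmi <- stats::rnorm(n, 30, 6)
  eta <- intercept + beta_age * (age - 53) + beta_bmi * (bmi - 30)
  y <- stats::rbinom(n, 1L, 1 / (1 + exp(-eta)))
  data.frame(subtype = ifelse(y == 1L, 1L, 3L), age = age, bmi = bmi)
}

#' Simulate targeted amplicon read counts
#'
#' Tumor alt reads are binomial(depth, vaf); matched-control alt reads
#' binomial(depth, error_rate).
#'
#' @param vaf Variant allele fraction(s) in the tumor.
#' @param depth Read depth (scalar or vector).
#' @param error_rate Sequencing error rate in the control.
#' @param seed Optional seed.
#' @return Data frame \code{alt_t}, \code{ref_t}, \code{alt_c},
#'   \code{ref_c}.
#' @export
simulate_tas_reads <- function(vaf, depth, error_rate = 1e-3, seed = NULL) {
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  if (any(depth <= 0)) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(vaf), length(depth))
  vaf <- rep_len(vaf, n); depth <- rep_len(as.integer(depth), n)
  alt_t <- stats::rbinom(n, depth, vaf)
  alt_c <- stats::rbinom(n, depth, error_rate)
  data.frame(alt_t = alt_t, ref_t = depth - alt_t,
             alt_c = alt_c, ref_c = depth - alt_c)
}

# --- scar-event planting ---------------------------------------------------

# per-genome capacity for planted events given the block geometry below:
# a TAI block takes 35 Mb of an arm (telomere slot, one per arm), an LOH
# block 30 Mb, an LST block 34 Mb; 1 Mb per arm is held back.
scar_capacity <- function(annotation) {
  arm_mb <- pmin(annotation$cen_start - 1,
                 annotation$length - annotation$cen_end) / 1e6
  arms <- 2L * nrow(annotation)
  list(tai = arms, total_budget_mb = sum(rep(arm_mb, each = 2L) - 1))
}

#' Plant allele-specific segments realizing exact scar-component counts
#'
#' Constructs a whole-genome segment table for one sample in which the
#' LOH, TAI and LST scar components equal the requested counts exactly:
#' interior >15 Mb copy-neutral-LOH blocks, telomeric allelic-imbalance
#' blocks that stop short of the centromere, and adjacent 12 Mb
#' state-transition pairs, each insulated by short balanced spacer
#' segments so no event contributes to another component.
#'
#' @param sample_id Sample label.
#' @param n_loh,n_tai,n_lst Target component counts.
#' @param annotation Genome annotation (arm capacity: one TAI and two
#'   interior events per arm).
#' @return Segment data frame covering every chromosome.
#' @export
plant_scar_segments <- function(sample_id, n_loh, n_tai, n_lst,
                                annotation = toy_genome(22L)) {
  cap <- scar_capacity(annotation)
  if (n_tai > cap$tai ||
      35 * n_tai + 30 * n_loh + 34 * n_lst > cap$total_budget_mb) {
    stop("requested event counts exceed genome capacity")
  }
  arms <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    rbind(data.frame(chrom = a$chrom, from = 1, to = a$cen_start - 1,
                     tel_left = TRUE, stringsAsFactors = FALSE),
          data.frame(chrom = a$chrom, from = a$cen_end + 1, to = a$length,
                     tel_left = FALSE, stringsAsFactors = FALSE))
  }))
  n_arms <- nrow(arms)
  budget <- (arms$to - arms$from + 1) - 1e6
  # TAI: one telomere slot per arm; interior events by first fit
  tai_arms <- if (n_tai > 0) seq_len(n_tai) else integer(0)
  budget[tai_arms] <- budget[tai_arms] - 35e6
  if (any(budget < 0)) stop("arms too short for telomeric events")
  interior <- c(rep("lst", n_lst), rep("loh", n_loh))
  interior_arms <- integer(length(interior))
  need <- ifelse(interior == "lst", 34e6, 30e6)
  for (j in seq_along(interior)) {
    fit <- which(budget >= need[j])
    if (!length(fit)) stop("requested event counts exceed genome capacity")
    interior_arms[j] <- fit[1]
    budget[fit[1]] <- budget[fit[1]] - need[j]
  }

  base_cn <- c(total = 2L, minor = 1L)
  spacer_pool <- list(c(6L, 3L), c(8L, 4L))
  segs <- list()
  for (ai in seq_len(n_arms)) {
    arm <- arms[ai, ]
    events <- interior[interior_arms == ai]
    has_tai <- ai %in% tai_arms
    pieces <- list()     # list of c(len, total, minor) laid from telomere
    sp <- 0L
    next_spacer <- function() {
      sp <<- sp + 1L
      spacer_pool[[(sp - 1L) %% 2L + 1L]]
    }
    if (has_tai) {
      pieces[[length(pieces) + 1L]] <- c(30e6, 3L, 1L)           # telomeric AI
      s <- next_spacer()
      pieces[[length(pieces) + 1L]] <- c(5e6, s[1], s[2])
    }
    for (ev in events) {
      s <- next_spacer()
      pieces[[length(pieces) + 1L]] <- c(5e6, s[1], s[2])
      if (ev == "loh") {
        pieces[[length(pieces) + 1L]] <- c(20e6, 1L, 0L)
      } else {
        pieces[[length(pieces) + 1L]] <- c(12e6, 4L, 2L)
        pieces[[length(pieces) + 1L]] <- c(12e6, 2L, 1L)
      }
      s <- next_spacer()
      pieces[[length(pieces) + 1L]] <- c(5e6, s[1], s[2])
    }
    used <- sum(vapply(pieces, `[`, numeric(1), 1L))
    arm_len <- arm$to - arm$from + 1
    if (used > arm_len - 1e6) stop("arm overfilled; reduce event counts")
    # remaining arm is diploid baseline
    lens <- vapply(pieces, `[`, numeric(1), 1L)
    tot <- vapply(pieces, `[`, numeric(1), 2L)
    mnr <- vapply(pieces, `[`, numeric(1), 3L)
    lens <- c(lens, arm_len - used)
    tot <- c(tot, base_cn["total"]); mnr <- c(mnr, base_cn["minor"])
    if (!arm$tel_left) { lens <- rev(lens); tot <- rev(tot); mnr <- rev(mnr) }
    ends <- arm$from - 1 + cumsum(lens)
    starts <- c(arm$from, utils::head(ends, -1) + 1)
    segs[[length(segs) + 1L]] <- data.frame(
      sample_id = sample_id, chrom = arm$chrom, start = starts, end = ends,
      total_cn = as.integer(tot), minor_cn = as.integer(mnr),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  # merge the two baseline pieces that meet across each centromere gap?
  # they do not touch (centromere interval separates them), keep as is
  validate_segments(out)
}

# --- indel channel realization --------------------------------------------

#' Construct a reference context realizing an ID83 channel
#'
#' Builds ref/alt alleles and flanking sequences whose classification
#' under [classify_indel()] is exactly the requested channel; used by the
#' cohort generator and as a round-trip oracle in tests.
#'
#' @param channel ID83 channel label.
#' @return One-row data frame: \code{ref}, \code{alt},
#'   \code{variant_class}, \code{flank5}, \code{flank3}, \code{hp_len}.
#' @export
indel_from_channel <- function(channel) {
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  lcat <- parts[1]; type <- parts[2]; sub <- parts[3]
  num <- as.integer(parts[4])
  bases <- c("A", "C", "G", "T")
  fill <- function(ch, n = 25L) strrep(ch, n)
  if (lcat == "1") {
    base <- sub                       # C or T (pyrimidine representation)
    kl <- num %/% 2L; kr <- num - kl
    other <- setdiff(bases, base)[1]
    flank5 <- paste0(fill(other), strrep(base, kl))
    flank3 <- paste0(strrep(base, kr), fill(other))
    if (type == "Del") {
      return(data.frame(ref = base, alt = "-", variant_class = "deletion",
                        flank5 = flank5, flank3 = flank3,
                        hp_len = num + 1L, stringsAsFactors = FALSE))
    }
    return(data.frame(ref = "-", alt = base, variant_class = "insertion",
                      flank5 = flank5, flank3 = flank3, hp_len = num,
                      stringsAsFactors = FALSE))
  }
  L <- if (lcat == "5") 5L else as.integer(lcat)
  if (sub == "M" && num >= L) L <- num + 1L  # MH length must be < true length
  unit <- paste(rep(c("C", "A", "T", "G"), length.out = L), collapse = "")
  first <- substr(unit, 1, 1); last <- substr(unit, L, L)
  x <- setdiff(bases, c(first, last))[1]   # left fill char
  y <- setdiff(bases, first)[1]            # right fill char
  if (sub == "R") {
    flank5 <- fill(x, 30L)
    flank3 <- paste0(strrep(unit, num), fill(y, 30L))
  } else {                                 # microhomology deletion
    nxt <- if (num < L) substr(unit, num + 1L, num + 1L) else ""
    y2 <- setdiff(bases, c(first, nxt))[1]
    flank5 <- fill(x, 30L)
    flank3 <- paste0(substr(unit, 1L, num), fill(y2, 30L))
  }
  if (type == "Del") {
    data.frame(ref = unit, alt = "-", variant_class = "deletion",
               flank5 = flank5, flank3 = flank3, hp_len = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(ref = "-", alt = unit, variant_class = "insertion",
               flank5 = flank5, flank3 = flank3, hp_len = NA_integer_,
               stringsAsFactors = FALSE)
  }
}

#' Write a cohort bundle to disk
#'
#' MAF-like TSV for truth mutations, SEG-like TSV for segments, clinical
#' CSV, and the full truth (config echo, exposures) as a JSON sidecar
#' when \pkg{jsonlite} is available.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$truth)) {
    write_maf(bundle$truth, file.path(dir, "truth_mutations.tsv"))
  }
  utils::write.table(bundle$segments, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$patients, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(bundle$exposures_true),
               bundle$exposures_true, check.names = FALSE),
    file.path(dir, "exposures_true.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- list(seed = bundle$config$seed,
                  n_patients = bundle$config$n_patients,
                  subtype_truth = bundle$patients$subtype_truth,
                  hrd_truth = bundle$patients$hrd_score_truth)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
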