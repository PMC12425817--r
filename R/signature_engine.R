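#' Cosine similarity
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine of the angle between \code{x} and \code{y}; 0 when
#'   either vector is all zero.
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' SBS96 channel of a single-base substitution
#'
#' Substitutions with a purine reference base are reverse-complemented so
#' that every channel is expressed on the pyrimidine strand.
#'
#' @param ref,alt Reference and alternate bases.
#' @param context Trinucleotide reference context with the mutated base in
#'   the middle (as sequenced, not pre-collapsed).
#' @return Channel label such as \code{"A[C>T]G"}, or NA when the context
#'   is ambiguous.
#' @export
sbs_channel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    nchar(context) == 3L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") & ref != alt &
    !grepl("[^ACGT]", context) & substr(context, 2, 2) == ref
  if (any(ok)) {
    r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
    pur <- r %in% c("A", "G")
    r[pur] <- chartr("AG", "TC", r[pur])
    a[pur] <- chartr("ACGT", "TGCA", a[pur])
    ctx[pur] <- revcomp(ctx[pur])
    out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  }
  out
}

#' Build a sample x channel SBS96 context matrix
#'
#' @param mutations Mutation table; SNV rows are used. A precomputed
#'   \code{channel} column is honored, otherwise channels are derived from
#'   \code{ref}, \code{alt} and \code{context} via [sbs_channel()].
#' @param sample_ids Optional sample universe (rows).
#' @return Integer matrix samples x 96 in canonical channel order, with an
#'   \code{excluded} attribute counting SNVs with unresolvable context.
#' @export
build_sbs_matrix <- function(mutations, sample_ids = NULL) {
  snv <- mutations[mutations$variant_class == "SNV", , drop = FALSE]
  channels <- sbs96_channels()
  if ("channel" %in% names(snv) && !all(is.na(snv$channel))) {
    chan <- snv$channel
  } else {
    chan <- sbs_channel(snv$ref, snv$alt, snv$context)
  }
  bad <- is.na(chan) | !chan %in% channels
  if (is.null(sample_ids)) sample_ids <- sort(unique(snv$sample_id))
  tab <- table(factor(snv$sample_id[!bad], levels = sample_ids),
               factor(chan[!bad], levels = channels))
  m <- matrix(as.integer(tab), nrow = length(sample_ids),
              dimnames = list(sample_ids, channels))
  attr(m, "excluded") <- sum(bad)
  m
}

#' ID83 channel of a small insertion/deletion
#'
#' Implements the COSMIC ID83 rules: 1-bp events are classified by the
#' pyrimidine identity of the inserted/deleted base and the homopolymer
#' run at the site; longer events by length (2, 3, 4, 5+) and the number
#' of tandem copies of the event sequence in the flanking reference;
#' deletions of 2+ bp with no flanking repeat copy are classified by
#' microhomology length when the deletion junction shares sequence with
#' the deleted segment.
#'
#' @param ref,alt Reference/alternate alleles (anchor-base or \code{"-"}
#'   conventions both accepted).
#' @param flank5,flank3 Flanking reference sequence on each side of the
#'   event (25 bp recommended; at least 5 copies of the event length are
#'   required to resolve repeat channels).
#' @return Channel label (e.g. \code{"1:Del:T:4"}, \code{"4:Del:M:2"}),
#'   or NA when unclassifiable.
#' @export
classify_indel <- function(ref, alt, flank5, flank3) {
  n <- max(length(ref), length(alt), length(flank5), length(flank3))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  flank5 <- rep_len(toupper(flank5), n); flank3 <- rep_len(toupper(flank3), n)
  vapply(seq_len(n), function(i) {
    classify_indel_one(ref[i], alt[i], flank5[i], flank3[i])
  }, character(1))
}

classify_indel_one <- function(ref, alt, flank5, flank3) {
  seq <- indel_changed_seq(ref, alt)
  if (is.na(seq) || seq == "" || grepl("[^ACGT]", seq)) return(NA_character_)
  is_del <- nchar(gsub("-", "", ref)) > nchar(gsub("-", "", alt))
  L <- nchar(seq)
  if (is.na(flank5) || is.na(flank3) ||
      nchar(flank5) < min(5L * L, 25L) || nchar(flank3) < min(5L * L, 25L)) {
    return(NA_character_)
  }
  type <- if (is_del) "Del" else "Ins"
  if (L == 1L) {
    base <- seq
    run <- count_runs_end(flank5, base) + count_runs_start(flank3, base)
    pyr <- if (base %in% c("A", "G")) chartr("AG", "TC", base) else base
    return(paste0("1:", type, ":", pyr, ":", min(run, 5L)))
  }
  lcat <- if (L >= 5L) "5" else as.character(L)
  reps <- count_unit_end(flank5, seq) + count_unit_start(flank3, seq)
  if (reps >= 1L) return(paste0(lcat, ":", type, ":R:", min(reps, 5L)))
  if (is_del) {
    mh <- max(common_prefix(seq, flank3), common_suffix(seq, flank5))
    mh <- min(mh, L - 1L, 5L)
    if (mh >= 1L) return(paste0(lcat, ":Del:M:", mh))
  }
  paste0(lcat, ":", type, ":R:0")
}

count_runs_start <- function(s, b) {
  chars <- strsplit(s, "")[[1]]
  r <- 0L
  for (ch in chars) { if (identical(ch, b)) r <- r + 1L else break }
  r
}
count_runs_end <- function(s, b) {
  count_runs_start(paste(rev(strsplit(s, "")[[1]]), collapse = ""), b)
}
count_unit_start <- function(s, unit) {
  L <- nchar(unit); r <- 0L; pos <- 1L
  while (pos + L - 1L <= nchar(s) && substr(s, pos, pos + L - 1L) == unit) {
    r <- r + 1L; pos <- pos + L
  }
  r
}
count_unit_end <- function(s, unit) {
  count_unit_start(paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                   paste(rev(strsplit(unit, "")[[1]]), collapse = ""))
}
common_prefix <- function(a, b) {
  k <- 0L
  for (i in seq_len(min(nchar(a), nchar(b)))) {
    if (substr(a, i, i) == substr(b, i, i)) k <- k + 1L else break
  }
  k
}
common_suffix <- function(a, b) {
  common_prefix(paste(rev(strsplit(a, "")[[1]]), collapse = ""),
                paste(rev(strsplit(b, "")[[1]]), collapse = ""))
}

#' Build a sample x channel ID83 context matrix
#'
#' @param mutations Mutation table; insertion/deletion rows are used. A
#'   precomputed \code{channel} column is honored, otherwise channels are
#'   derived from \code{ref}/\code{alt} and \code{flank5}/\code{flank3}.
#' @param sample_ids Optional sample universe (rows).
#' @return Integer matrix samples x 83 with an \code{excluded} attribute.
#' @export
build_id_matrix <- function(mutations, sample_ids = NULL) {
  ind <- mutations[mutations$variant_class %in% c("insertion", "deletion"), ,
                   drop = FALSE]
  channels <- id83_channels()
  if ("channel" %in% names(ind) && !all(is.na(ind$channel))) {
    chan <- ind$channel
  } else {
    chan <- classify_indel(ind$ref, ind$alt, ind$flank5, ind$flank3)
  }
  bad <- is.na(chan) | !chan %in% channels
  if (is.null(sample_ids)) sample_ids <- sort(unique(ind$sample_id))
  tab <- table(factor(ind$sample_id[!bad], levels = sample_ids),
               factor(chan[!bad], levels = channels))
  m <- matrix(as.integer(tab), nrow = length(sample_ids),
              dimnames = list(sample_ids, channels))
  attr(m, "excluded") <- sum(bad)
  m
}

# KL-divergence NMF by multiplicative updates. V is channels x samples.
# Returns column-stochastic W (channels x k) and H (k x samples) in count
# units, plus the KL objective trace.
nmf_kl <- function(V, k, max_iter = 2000L, tol = 1e-8, W0 = NULL, H0 = NULL) {
  eps <- 1e-12
  m <- nrow(V); n <- ncol(V)
  W <- if (is.null(W0)) matrix(stats::runif(m * k, 0.1, 1), m, k) else W0
  H <- if (is.null(H0)) matrix(stats::runif(k * n, 0.1, 1), k, n) else H0
  kl <- function(WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  WH <- W %*% H
  obj <- kl(WH)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- W * ((V / (WH + eps)) %*% t(H)) / pmax(matrix(rowSums(H), m, k,
                                                       byrow = TRUE), eps)
    WH <- W %*% H
    H <- H * (t(W) %*% (V / (WH + eps))) / pmax(matrix(colSums(W), k, n), eps)
    WH <- W %*% H
    new_obj <- kl(WH)
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(obj - new_obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj; converged <- TRUE; break
    }
    obj <- new_obj
  }
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2L, s, "/")
  H <- H * s
  list(W = W, H = H, objective = obj, trace = trace, converged = converged)
}

# greedy one-to-one matching of columns of A to columns of B by cosine
match_columns <- function(A, B) {
  k <- ncol(A)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- cosine_similarity(A[, i], B[, j])
  }
  assign <- integer(k)
  used_a <- logical(k); used_b <- logical(k)
  for (step in seq_len(k)) {
    sim2 <- sim
    sim2[used_a, ] <- -Inf; sim2[, used_b] <- -Inf
    ij <- arrayInd(which.max(sim2), dim(sim2))
    assign[ij[1]] <- ij[2]
    used_a[ij[1]] <- TRUE; used_b[ij[2]] <- TRUE
  }
  assign  # assign[i] = centroid index for column i of A
}

#' De novo mutational-signature extraction with stability selection
#'
#' For each candidate rank k, KL-divergence NMF (Poisson-consistent
#' multiplicative updates) is run on \code{n_replicates} bootstrap
#' resamples of the context matrix from random initializations. Replicate
#' signatures are clustered by cosine similarity with a one-per-replicate
#' matching; per-signature stability is the mean silhouette width of the
#' cluster (cosine distance). The selected rank is the largest k whose
#' mean silhouette reaches \code{sil_min} with no two consensus
#' signatures nearly collinear (cosine >= 0.95, a degenerate split).
#'
#' @param mat Context matrix, samples x channels (as produced by
#'   [build_sbs_matrix()]).
#' @param k_range Candidate ranks.
#' @param n_replicates Bootstrap replicates per rank.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param max_iter Maximum multiplicative updates per fit.
#' @param sil_min Stability threshold for rank selection.
#' @return List with \code{selected_k}, \code{models} (one per k:
#'   \code{signatures} channels x k column-stochastic, \code{exposures}
#'   samples x k in mutation counts, \code{stability} per signature,
#'   \code{mean_silhouette}, \code{degenerate}, \code{reconstruction_cosine},
#'   \code{converged}), and the selected \code{model}.
#' @export
extract_denovo <- function(mat, k_range = 1:6, n_replicates = 10L,
                           seed = 1L, max_iter = 2000L, sil_min = 0.8) {
  stopifnot(nrow(mat) >= 2L, all(mat >= 0))
  if (any(k_range < 1L) || any(k_range > min(dim(mat)))) {
    stop("k_range must lie within [1, min(channels, samples)]")
  }
  set.seed(seed)
  V <- t(mat)  # channels x samples
  totals <- colSums(V)
  if (any(totals == 0)) {
    stop("context matrix contains empty samples; drop them first")
  }
  models <- list()
  for (k in sort(k_range)) {
    fits <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      Vb <- vapply(seq_len(ncol(V)), function(j) {
        as.numeric(stats::rmultinom(1L, size = totals[j],
                                    prob = V[, j] / totals[j]))
      }, numeric(nrow(V)))
      fits[[r]] <- nmf_kl(Vb, k, max_iter = max_iter)
    }
    if (k == 1L) {
      centroids <- matrix(rowMeans(vapply(fits, function(f) f$W[, 1],
                                          numeric(nrow(V)))), ncol = 1L)
      centroids <- centroids / sum(centroids)
      mean_sil <- 1
      stability <- 1
      degenerate <- FALSE
    } else {
      ref <- which.min(vapply(fits, function(f) f$objective, numeric(1)))
      centroids <- fits[[ref]]$W
      labels <- NULL
      for (pass in 1:4) {
        sums <- matrix(0, nrow(V), k); counts <- integer(k)
        labels <- matrix(0L, n_replicates, k)
        for (r in seq_len(n_replicates)) {
          asg <- match_columns(fits[[r]]$W, centroids)
          labels[r, ] <- asg
          for (i in seq_len(k)) {
            sums[, asg[i]] <- sums[, asg[i]] + fits[[r]]$W[, i]
            counts[asg[i]] <- counts[asg[i]] + 1L
          }
        }
        centroids <- sweep(sums, 2L, pmax(counts, 1L), "/")
        centroids <- sweep(centroids, 2L, colSums(centroids), "/")
      }
      allW <- do.call(cbind, lapply(fits, function(f) f$W))
      lab_vec <- as.integer(t(labels))
      cs <- crossprod(allW / sqrt(matrix(colSums(allW^2), nrow(allW),
                                         ncol(allW), byrow = TRUE)))
      cs[cs > 1] <- 1
      sil <- cluster::silhouette(lab_vec, dmatrix = 1 - cs)
      mean_sil <- mean(sil[, "sil_width"])
      stability <- vapply(seq_len(k), function(i)
        mean(sil[lab_vec == i, "sil_width"]), numeric(1))
      cc <- crossprod(sweep(centroids, 2L, sqrt(colSums(centroids^2)), "/"))
      degenerate <- any(cc[upper.tri(cc)] >= 0.95)
    }
    colnames(centroids) <- paste0("DN", seq_len(ncol(centroids)))
    expo <- t(kl_refit_exposures(V, centroids))
    rownames(expo) <- rownames(mat)
    colnames(expo) <- colnames(centroids)
    recon <- centroids %*% t(expo)
    rec_cos <- mean(vapply(seq_len(ncol(V)), function(j)
      cosine_similarity(V[, j], recon[, j]), numeric(1)))
    rownames(centroids) <- colnames(mat)
    models[[as.character(k)]] <- list(
      k = k, signatures = centroids, exposures = expo,
      stability = stability, mean_silhouette = mean_sil,
      degenerate = degenerate, reconstruction_cosine = rec_cos,
      converged = all(vapply(fits, function(f) f$converged, logical(1))))
  }
  sils <- vapply(models, function(m) m$mean_silhouette, numeric(1))
  degs <- vapply(models, function(m) m$degenerate, logical(1))
  ks <- vapply(models, function(m) m$k, numeric(1))
  ok <- sils >= sil_min & !degs
  selected_k <- if (any(ok)) max(ks[ok]) else ks[which.max(sils)]
  list(selected_k = as.integer(selected_k), models = models,
       model = models[[as.character(selected_k)]])
}

# KL (Poisson) exposure refit with signatures held fixed; for
# column-stochastic W the fixed point conserves per-sample totals
kl_refit_exposures <- function(V, W, max_iter = 1000L, tol = 1e-10) {
  eps <- 1e-12
  k <- ncol(W); n <- ncol(V)
  H <- matrix(colSums(V) / k, k, n, byrow = TRUE)
  cw <- pmax(matrix(colSums(W), k, n), eps)
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    Hn <- H * (t(W) %*% (V / (WH + eps))) / cw
    if (max(abs(Hn - H)) <= tol * max(1, max(H))) { H <- Hn; break }
    H <- Hn
  }
  H
}

nnls_fit <- function(v, X) {
  if (all(v == 0)) return(numeric(ncol(X)))
  as.numeric(pracma::lsqnonneg(X, v)$x)
}

#' Decompose mutation catalogs onto a reference signature catalog
#'
#' Each sample (or de novo signature) is fitted by non-negative least
#' squares against the reference catalog, then sparsified by backward
#' elimination: the reference signature whose removal costs the least
#' reconstruction cosine is dropped (refitting after each removal) for as
#' long as the cost stays below \code{drop_tol}.
#'
#' @param x Samples x channels count matrix, or a numeric channel vector
#'   for a single sample.
#' @param catalog Channels x signatures column-stochastic reference
#'   catalog with the same channel ordering.
#' @param drop_tol Maximum tolerated loss of reconstruction cosine when
#'   removing one reference signature.
#' @return Exposure matrix samples x reference signatures, in mutation
#'   counts, with a \code{reconstruction_cosine} attribute (per sample).
#' @export
decompose_to_reference <- function(x, catalog, drop_tol = 0.01) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list("sample", names(x)))
  if (ncol(x) != nrow(catalog)) stop("channel dimensions do not match")
  if (!is.null(colnames(x)) && !is.null(rownames(catalog)) &&
      !identical(colnames(x), rownames(catalog))) {
    if (!setequal(colnames(x), rownames(catalog))) {
      stop("channel labels do not match the catalog")
    }
    x <- x[, rownames(catalog), drop = FALSE]
  }
  nsig <- ncol(catalog)
  expo <- matrix(0, nrow(x), nsig, dimnames = list(rownames(x),
                                                   colnames(catalog)))
  rc <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- as.numeric(x[i, ])
    if (all(v == 0)) { rc[i] <- NA_real_; next }
    active <- seq_len(nsig)
    coef <- nnls_fit(v, catalog[, active, drop = FALSE])
    cos_full <- cosine_similarity(v, catalog[, active, drop = FALSE] %*% coef)
    while (length(active) > 1L) {
      trial <- lapply(seq_along(active), function(j) {
        a2 <- active[-j]
        cf <- nnls_fit(v, catalog[, a2, drop = FALSE])
        list(active = a2, coef = cf,
             cos = cosine_similarity(v, catalog[, a2, drop = FALSE] %*% cf))
      })
      costs <- cos_full - vapply(trial, function(t) t$cos, numeric(1))
      j <- which.min(costs)
      if (costs[j] < drop_tol) {
        active <- trial[[j]]$active
        coef <- trial[[j]]$coef
        cos_full <- trial[[j]]$cos
      } else break
    }
    expo[i, active] <- coef
    rc[i] <- cos_full
  }
  attr(expo, "reconstruction_cosine") <- rc
  expo
}

#' Pearson correlations between signature exposures and covariates
#'
#' @param exposures Samples x signatures matrix or data frame.
#' @param covariates Samples x covariates matrix or data frame (same row
#'   order).
#' @return Data frame \code{signature}, \code{covariate}, \code{n},
#'   \code{r}, \code{p} (two-sided, t distribution); r is NA when either
#'   variable has zero variance or fewer than 3 complete pairs.
#' @export
exposure_correlations <- function(exposures, covariates) {
  exposures <- as.data.frame(exposures)
  covariates <- as.data.frame(covariates)
  if (nrow(exposures) != nrow(covariates)) stop("row counts differ")
  out <- expand.grid(signature = names(exposures),
                     covariate = names(covariates),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- exposures[[out$signature[i]]]
    y <- covariates[[out$covariate[i]]]
    ok <- stats::complete.cases(x, y)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      out$r[i] <- unname(ct$estimate)
      out$p[i] <- ct$p.value
    }
  }
  out
}
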