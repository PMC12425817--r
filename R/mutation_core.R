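#' Construct and validate a somatic mutation table
#'
#' The package represents somatic mutations as a plain data frame (one row
#' per variant call) in a MAF-like layout. Required columns:
#' \code{sample_id}, \code{chrom}, \code{pos} (1-based), \code{ref},
#' \code{alt}, \code{variant_class} (one of \code{"SNV"},
#' \code{"insertion"}, \code{"deletion"}, \code{"MNV"}). Optional evidence
#' and annotation columns (filled with \code{NA} when absent):
#' \code{gene}, \code{consequence}, \code{nonsilent} (logical),
#' \code{callers} (comma-separated caller names), \code{t_alt},
#' \code{t_ref}, \code{n_alt}, \code{n_ref} (tumor/normal read counts),
#' \code{alt_fwd}, \code{alt_rev}, \code{ref_fwd}, \code{ref_rev}
#' (strand-resolved counts), \code{site_bq}, \code{flank_bq} (mean base
#' quality at the site and in the flanks), \code{alt_mq} (mean mapping
#' quality of alt-carrying reads), \code{context} (pyrimidine-agnostic
#' trinucleotide context for SNVs) and \code{hp_len} (homopolymer run
#' length at an indel site).
#'
#' @param df Data frame with at least the required columns.
#' @return The validated data frame with all optional columns present.
#' @export
mutation_records <- function(df) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  opt_chr <- c("gene", "consequence", "callers", "context")
  opt_num <- c("t_alt", "t_ref", "n_alt", "n_ref", "alt_fwd", "alt_rev",
               "ref_fwd", "ref_rev", "site_bq", "flank_bq", "alt_mq", "hp_len")
  for (cn in opt_chr) if (!cn %in% names(df)) df[[cn]] <- rep(NA_character_, nrow(df))
  if (!"nonsilent" %in% names(df)) df$nonsilent <- rep(NA, nrow(df))
  for (cn in opt_num) if (!cn %in% names(df)) df[[cn]] <- rep(NA_real_, nrow(df))
  bad <- df$ref == df$alt & df$variant_class == "SNV"
  if (any(bad, na.rm = TRUE)) stop("ref equals alt for ", sum(bad), " SNV record(s)")
  counts <- as.matrix(df[, opt_num])
  if (any(counts < 0, na.rm = TRUE)) stop("negative evidence counts")
  df
}

variant_key <- function(df) {
  paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = "\r")
}

#' Merge per-caller somatic call sets
#'
#' Records are merged on (sample, chrom, pos, ref, alt); the
#' \code{callers} field becomes the union of supporting callers and
#' records supported by fewer than \code{min_support} callers are
#' dropped. Evidence fields are taken from the supporting record with the
#' greatest tumor depth. Conflicting reference alleles at the same locus
#' raise an error.
#'
#' @param call_sets Named list of mutation tables, one per caller.
#' @param min_support Minimum number of supporting callers to retain a
#'   variant. The default 1 takes the union, leaving specificity to the
#'   evidence filters.
#' @return Merged mutation table with a \code{n_callers} column.
#' @export
integrate_callers <- function(call_sets, min_support = 1L) {
  if (!length(call_sets)) stop("no call sets supplied")
  if (is.null(names(call_sets)) || any(names(call_sets) == "")) {
    stop("call_sets must be a named list (caller names)")
  }
  samp <- lapply(call_sets, function(x) sort(unique(x$sample_id)))
  all_records <- do.call(rbind, lapply(names(call_sets), function(cl) {
    x <- mutation_records(call_sets[[cl]])
    x$callers <- cl
    x
  }))
  if (!nrow(all_records)) return(all_records)
  loc_key <- paste(all_records$sample_id, all_records$chrom, all_records$pos, sep = "\r")
  refs_by_loc <- tapply(all_records$ref, loc_key, function(r) length(unique(r)))
  if (any(refs_by_loc > 1)) {
    stop("conflicting reference alleles at ", sum(refs_by_loc > 1), " locus/loci")
  }
  key <- variant_key(all_records)
  split_idx <- split(seq_len(nrow(all_records)), key)
  merged <- lapply(split_idx, function(idx) {
    sub <- all_records[idx, , drop = FALSE]
    depth <- sub$t_alt + sub$t_ref
    best <- if (all(is.na(depth))) 1L else which.max(depth)
    rec <- sub[best, , drop = FALSE]
    rec$callers <- paste(sort(unique(sub$callers)), collapse = ",")
    rec$n_callers <- length(unique(sub$callers))
    rec
  })
  out <- do.call(rbind, merged)
  out <- out[out$n_callers >= min_support, , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filtering thresholds for somatic variant evidence filters
#'
#' @param alpha_normal Significance level for the tumor-vs-normal
#'   contingency test: a variant with alt reads in the normal is kept only
#'   when the tumor/normal contrast is significant at this level.
#' @param alpha_strand Significance level for the strand-bias test.
#' @param bq_drop Maximum tolerated drop (Phred) of site base quality
#'   below the flanking mean.
#' @param mq_min Minimum mean mapping quality of alt-carrying reads.
#' @param hp_max Homopolymer run length at which 1-bp indels are rejected.
#' @return List of thresholds.
#' @export
filter_params <- function(alpha_normal = 0.05, alpha_strand = 0.05,
                          bq_drop = 10, mq_min = 20, hp_max = 6L) {
  stopifnot(alpha_normal > 0, alpha_normal < 1, alpha_strand > 0,
            alpha_strand < 1, bq_drop >= 0, mq_min >= 0, hp_max >= 1)
  list(alpha_normal = alpha_normal, alpha_strand = alpha_strand,
       bq_drop = bq_drop, mq_min = mq_min, hp_max = as.integer(hp_max))
}

#' Evidence-based filtering of putative somatic SNVs
#'
#' Applies the four standard false-call criteria, accumulating reasons
#' rather than short-circuiting:
#' \describe{
#'   \item{normal_evidence}{alt allele present in the matched normal and
#'     the tumor-vs-normal contingency (two-sided Fisher exact on
#'     alt/ref x tumor/normal) is \emph{not} significant at
#'     \code{alpha_normal};}
#'   \item{strand_bias}{all alt reads on a single strand and the
#'     alt-vs-ref strand contingency is significant at
#'     \code{alpha_strand};}
#'   \item{base_quality_drop}{mean base quality at the site at least
#'     \code{bq_drop} Phred below the flanking mean;}
#'   \item{poor_mapping}{mean mapping quality of alt reads below
#'     \code{mq_min}.}
#' }
#' Records with missing evidence for a criterion are flagged
#' \code{unevaluable} and reported separately rather than silently passed.
#'
#' @param records Mutation table (SNV rows are evaluated; other classes
#'   are passed through untouched with \code{passed = NA}).
#' @param params Thresholds from [filter_params()].
#' @return Data frame of filter decisions: the variant key columns,
#'   \code{passed}, \code{reasons} (comma-separated), \code{unevaluable}.
#' @export
filter_snvs <- function(records, params = filter_params()) {
  records <- mutation_records(records)
  is_snv <- records$variant_class == "SNV"
  n <- nrow(records)
  reasons <- vector("list", n)
  unevaluable <- logical(n)
  idx <- which(is_snv)
  if (length(idx)) {
    r <- records[idx, , drop = FALSE]
    need_tn <- c("t_alt", "t_ref", "n_alt", "n_ref")
    need_strand <- c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev")
    miss_tn <- rowSums(is.na(r[, need_tn])) > 0
    miss_strand <- rowSums(is.na(r[, need_strand])) > 0
    miss_bq <- is.na(r$site_bq) | is.na(r$flank_bq)
    miss_mq <- is.na(r$alt_mq)

    fail_normal <- rep(FALSE, nrow(r))
    cand <- !miss_tn & r$n_alt > 0
    if (any(cand)) {
      p <- fisher_p(r$t_alt[cand], r$t_ref[cand], r$n_alt[cand], r$n_ref[cand])
      fail_normal[cand] <- p >= params$alpha_normal
    }
    fail_strand <- rep(FALSE, nrow(r))
    one_strand <- !miss_strand & (r$alt_fwd + r$alt_rev) > 0 &
      (r$alt_fwd == 0 | r$alt_rev == 0)
    if (any(one_strand)) {
      p <- fisher_p(r$alt_fwd[one_strand], r$alt_rev[one_strand],
                    r$ref_fwd[one_strand], r$ref_rev[one_strand])
      fail_strand[one_strand] <- p < params$alpha_strand
    }
    fail_bq <- !miss_bq & (r$site_bq < r$flank_bq - params$bq_drop)
    fail_mq <- !miss_mq & (r$alt_mq < params$mq_min)

    for (j in seq_along(idx)) {
      rs <- character(0)
      if (fail_normal[j]) rs <- c(rs, "normal_evidence")
      if (fail_strand[j]) rs <- c(rs, "strand_bias")
      if (fail_bq[j]) rs <- c(rs, "base_quality_drop")
      if (fail_mq[j]) rs <- c(rs, "poor_mapping")
      reasons[[idx[j]]] <- rs
      unevaluable[idx[j]] <- miss_tn[j] || miss_strand[j] || miss_bq[j] || miss_mq[j]
    }
  }
  out <- data.frame(
    sample_id = records$sample_id, chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt,
    passed = NA, reasons = vapply(reasons, function(x)
      paste(x, collapse = ","), character(1)),
    unevaluable = unevaluable, stringsAsFactors = FALSE)
  out$passed[is_snv] <- !unevaluable[is_snv] & out$reasons[is_snv] == ""
  out$passed[is_snv & unevaluable] <- NA
  out
}

#' Evidence-based filtering of putative somatic indels
#'
#' A 1-bp indel is rejected when it sits in a homopolymer run of length
#' \code{hp_max} or more (\code{homopolymer} reason); any indel is also
#' rejected on the normal-evidence contingency rule or on poor mapping
#' quality, with the same thresholds as [filter_snvs()]. Homopolymer run
#' length is taken from the \code{hp_len} column, or computed from
#' \code{flank5}/\code{flank3} sequence columns when present.
#'
#' @inheritParams filter_snvs
#' @return Data frame of filter decisions (same layout as [filter_snvs()]).
#' @export
filter_indels <- function(records, params = filter_params()) {
  records <- mutation_records(records)
  is_indel <- records$variant_class %in% c("insertion", "deletion")
  n <- nrow(records)
  hp <- records$hp_len
  if (all(is.na(hp)) && all(c("flank5", "flank3") %in% names(records))) {
    hp <- mapply(homopolymer_run, records$ref, records$alt,
                 records$variant_class, records$flank5, records$flank3)
  }
  reasons <- vector("list", n)
  unevaluable <- logical(n)
  for (i in which(is_indel)) {
    rs <- character(0)
    seq <- indel_changed_seq(records$ref[i], records$alt[i])
    len <- if (is.na(seq)) NA_integer_ else nchar(seq)
    if (is.na(len)) len <- abs(nchar(gsub("-", "", records$ref[i])) -
                                 nchar(gsub("-", "", records$alt[i])))
    if (len == 1L) {
      if (is.na(hp[i])) unevaluable[i] <- TRUE
      else if (hp[i] >= params$hp_max) rs <- c(rs, "homopolymer")
    }
    if (!is.na(records$n_alt[i]) && records$n_alt[i] > 0 &&
        !any(is.na(records[i, c("t_alt", "t_ref", "n_ref")]))) {
      p <- fisher_p(records$t_alt[i], records$t_ref[i],
                    records$n_alt[i], records$n_ref[i])
      if (p >= params$alpha_normal) rs <- c(rs, "normal_evidence")
    }
    if (!is.na(records$alt_mq[i]) && records$alt_mq[i] < params$mq_min) {
      rs <- c(rs, "poor_mapping")
    }
    reasons[[i]] <- rs
  }
  out <- data.frame(
    sample_id = records$sample_id, chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt,
    passed = NA, reasons = vapply(reasons, function(x)
      paste(x, collapse = ","), character(1)),
    unevaluable = unevaluable, stringsAsFactors = FALSE)
  out$passed[is_indel] <- !unevaluable[is_indel] & out$reasons[is_indel] == ""
  out$passed[is_indel & unevaluable] <- NA
  out
}

#' Homopolymer run length at an indel site
#'
#' For a 1-bp insertion or deletion of base \code{B}, the length of the
#' uninterrupted run of \code{B} at the site: flanking copies on both
#' sides plus, for a deletion, the deleted base itself.
#'
#' @param ref,alt Reference and alternate alleles (anchor-base free, i.e.
#'   \code{ref = "A", alt = "-"} style or \code{ref = "CA", alt = "C"}
#'   MAF style both accepted).
#' @param variant_class "insertion" or "deletion".
#' @param flank5,flank3 Flanking reference sequence 5' and 3' of the site.
#' @return Integer run length (NA for non-1-bp events).
#' @export
homopolymer_run <- function(ref, alt, variant_class, flank5, flank3) {
  seq <- indel_changed_seq(ref, alt)
  if (is.na(seq) || nchar(seq) != 1L) return(NA_integer_)
  run_end <- function(s, b) {
    chars <- rev(strsplit(s, "")[[1]])
    r <- 0L
    for (ch in chars) { if (ch == b) r <- r + 1L else break }
    r
  }
  run_start <- function(s, b) {
    chars <- strsplit(s, "")[[1]]
    r <- 0L
    for (ch in chars) { if (ch == b) r <- r + 1L else break }
    r
  }
  base <- seq
  run_end(flank5, base) + run_start(flank3, base) +
    if (variant_class == "deletion") 1L else 0L
}

# inserted/deleted bases from a ref/alt pair, tolerant of anchor bases
indel_changed_seq <- function(ref, alt) {
  ref <- gsub("-", "", ref); alt <- gsub("-", "", alt)
  if (nchar(ref) > nchar(alt)) {
    if (alt != "" && substr(ref, 1, nchar(alt)) == alt) {
      substr(ref, nchar(alt) + 1L, nchar(ref))
    } else if (alt == "") ref else NA_character_
  } else if (nchar(alt) > nchar(ref)) {
    if (ref != "" && substr(alt, 1, nchar(ref)) == ref) {
      substr(alt, nchar(ref) + 1L, nchar(alt))
    } else if (ref == "") alt else NA_character_
  } else {
    NA_character_
  }
}

#' Tumor mutational burden per sample
#'
#' Burden is the number of somatic SNVs per megabase of sequenced target.
#' A sample is flagged hypermutated when its burden exceeds
#' \code{hyper_cutoff} SNVs/Mb (strict \code{>} by default; set
#' \code{inclusive = TRUE} for a \code{>=} boundary).
#'
#' @param records Filtered mutation table.
#' @param target_size_mb Sequenced target size in Mb. The default 73.499
#'   is the capture-library footprint of the whole-exome design this
#'   pipeline was built around.
#' @param sample_ids Optional sample universe (samples with zero mutations
#'   are then reported with burden 0).
#' @param hyper_cutoff Hypermutation boundary in SNVs/Mb.
#' @param inclusive Use \code{>=} instead of \code{>} at the boundary.
#' @return Data frame: \code{sample_id}, \code{snv_count},
#'   \code{indel_count}, \code{target_size_mb}, \code{snvs_per_mb},
#'   \code{hypermutated}.
#' @export
mutation_burden <- function(records, target_size_mb = 73.499,
                            sample_ids = NULL, hyper_cutoff = 10,
                            inclusive = FALSE) {
  if (!is.numeric(target_size_mb) || target_size_mb <= 0) {
    stop("target_size_mb must be positive")
  }
  records <- mutation_records(records)
  if (is.null(sample_ids)) sample_ids <- sort(unique(records$sample_id))
  snv <- table(factor(records$sample_id[records$variant_class == "SNV"],
                      levels = sample_ids))
  ind <- table(factor(records$sample_id[records$variant_class %in%
                                          c("insertion", "deletion")],
                      levels = sample_ids))
  per_mb <- as.numeric(snv) / target_size_mb
  hyper <- if (inclusive) per_mb >= hyper_cutoff else per_mb > hyper_cutoff
  data.frame(sample_id = sample_ids, snv_count = as.integer(snv),
             indel_count = as.integer(ind), target_size_mb = target_size_mb,
             snvs_per_mb = per_mb, hypermutated = hyper,
             stringsAsFactors = FALSE)
}

#' Per-gene nonsilent mutation frequency
#'
#' A sample counts once per gene regardless of how many mutations it
#' carries there. Only records flagged nonsilent are counted (records
#' with \code{nonsilent = NA} are treated as nonsilent when the column is
#' entirely missing, otherwise excluded).
#'
#' @param records Filtered mutation table with \code{gene} populated.
#' @param n_samples Cohort size (denominator).
#' @param min_frequency Optional retention threshold (e.g. 0.02 keeps
#'   genes mutated in at least 2\% of samples).
#' @return Data frame \code{gene}, \code{mutated_samples},
#'   \code{frequency}, sorted by decreasing frequency.
#' @export
gene_frequency <- function(records, n_samples, min_frequency = NULL) {
  if (!is.numeric(n_samples) || n_samples <= 0) stop("n_samples must be positive")
  records <- mutation_records(records)
  if (!all(is.na(records$nonsilent))) {
    records <- records[!is.na(records$nonsilent) & records$nonsilent, , drop = FALSE]
  }
  records <- records[!is.na(records$gene), , drop = FALSE]
  pairs <- unique(records[, c("sample_id", "gene")])
  tab <- table(pairs$gene)
  out <- data.frame(gene = names(tab), mutated_samples = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$mutated_samples / n_samples
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(min_frequency)) {
    out <- out[out$frequency >= min_frequency, , drop = FALSE]
  }
  out
}

#' Cohort-level variant class summary
#'
#' Totals and integer-rounded percentages of SNVs and indels among all
#' coding mutations.
#'
#' @param records Mutation table.
#' @return List: \code{total}, \code{snv_count}, \code{indel_count},
#'   \code{mnv_count}, \code{pct_snv}, \code{pct_indel}.
#' @export
summarize_classes <- function(records) {
  if (!nrow(records)) {
    return(list(total = 0L, snv_count = 0L, indel_count = 0L, mnv_count = 0L,
                pct_snv = 0L, pct_indel = 0L))
  }
  records <- mutation_records(records)
  total <- nrow(records)
  snv <- sum(records$variant_class == "SNV")
  ind <- sum(records$variant_class %in% c("insertion", "deletion"))
  mnv <- sum(records$variant_class == "MNV")
  list(total = total, snv_count = snv, indel_count = ind, mnv_count = mnv,
       pct_snv = as.integer(round(100 * snv / total)),
       pct_indel = as.integer(round(100 * ind / total)))
}

#' Read / write MAF-like mutation tables
#'
#' Plain tab-separated files with the column layout of
#' [mutation_records()].
#'
#' @param path File path.
#' @return For \code{read_maf}, a validated mutation table.
#' @export
read_maf <- function(path) {
  mutation_records(utils::read.delim(path, stringsAsFactors = FALSE,
                                     check.names = FALSE))
}

#' @rdname read_maf
#' @param records Mutation table to write.
#' @export
write_maf <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
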