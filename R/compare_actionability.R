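#' Cross-cohort gene mutation-frequency comparison with FDR control
#'
#' Per gene, a two-sided Fisher exact test on mutated/unmutated counts in
#' the two cohorts; Benjamini-Hochberg q-values across all tested genes;
#' genes flagged at \code{q < q_threshold}.
#'
#' @param a,b Named lists/data frames describing each cohort: \code{n}
#'   (cohort size) and \code{counts} (named integer vector of per-gene
#'   mutated-sample counts). Genes absent from one cohort count 0 there.
#' @param q_threshold FDR flagging threshold.
#' @return Data frame \code{gene}, \code{count_a}, \code{count_b},
#'   \code{freq_a}, \code{freq_b}, \code{p}, \code{q}, \code{flagged}.
#' @export
compare_frequencies <- function(a, b, q_threshold = 0.10) {
  for (ch in list(a, b)) {
    if (is.null(ch$n) || ch$n <= 0) stop("cohort size n must be positive")
    if (any(ch$counts > ch$n)) stop("gene counts exceed cohort size")
  }
  genes <- sort(union(names(a$counts), names(b$counts)))
  ca <- ifelse(genes %in% names(a$counts), a$counts[genes], 0L)
  cb <- ifelse(genes %in% names(b$counts), b$counts[genes], 0L)
  p <- fisher_p(ca, a$n - ca, cb, b$n - cb)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, count_a = as.integer(ca), count_b = as.integer(cb),
             freq_a = ca / a$n, freq_b = cb / b$n, p = p, q = q,
             flagged = q < q_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Germline allele-frequency test against a reference population
#'
#' Chi-square test when all expected cell counts reach 5, Fisher exact
#' otherwise. \code{alternative = "greater"} gives the one-sided
#' enrichment test (always Fisher).
#'
#' @param case_alt,case_total Alt allele count and total alleles in cases.
#' @param ref_alt,ref_total Alt allele count and total alleles in the
#'   reference population.
#' @param alternative "two.sided" or "greater" (case enrichment).
#' @return List: \code{p}, \code{method}.
#' @export
germline_vs_reference <- function(case_alt, case_total, ref_alt, ref_total,
                                  alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (case_total <= 0 || ref_total <= 0) stop("totals must be positive")
  tab <- matrix(c(case_alt, case_total - case_alt,
                  ref_alt, ref_total - ref_alt), 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (alternative == "greater" || any(expected < 5)) {
    list(p = fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                      alternative = alternative),
         method = "fisher")
  } else {
    list(p = suppressWarnings(stats::chisq.test(tab)$p.value),
         method = "chisq")
  }
}

#' Discretize total copy number to a GISTIC-style threshold value
#'
#' Maps integer total copy number to \{-2, -1, 0, 1, 2\}: high-level
#' deletion, low-level deletion, diploid, low-level amplification,
#' high-level amplification. Default cuts: 0 -> -2, 1 -> -1, 2 -> 0,
#' 3-4 -> 1, >= \code{high_amp_min} -> 2.
#'
#' @param total_cn Non-negative integer copy number (vectorized).
#' @param high_amp_min Copy number at which an amplification becomes
#'   high-level.
#' @return Integer vector in \{-2, ..., 2\}.
#' @export
threshold_cn <- function(total_cn, high_amp_min = 5L) {
  if (any(is.na(total_cn)) || any(total_cn < 0)) {
    stop("total_cn must be non-negative")
  }
  out <- integer(length(total_cn))
  out[total_cn == 0] <- -2L
  out[total_cn == 1] <- -1L
  out[total_cn == 2] <- 0L
  out[total_cn > 2 & total_cn < high_amp_min] <- 1L
  out[total_cn >= high_amp_min] <- 2L
  out
}

#' CD274 (PD-L1) copy-number class
#'
#' @param value GISTIC threshold value in \{-2, ..., 2\}.
#' @return "gain" for value 1, "high_amp" for value 2, otherwise
#'   "neutral".
#' @export
cd274_class <- function(value) {
  if (any(!value %in% -2:2)) stop("value must be a GISTIC threshold value")
  ifelse(value == 2L, "high_amp", ifelse(value == 1L, "gain", "neutral"))
}

#' Count predicted neoantigens per sample
#'
#' A nonsynonymous missense mutation counts as a neoantigen source when
#' it has at least one predicted binder with IC50 below 500 nM and its
#' transcript shows expression (read count >= 1). Mutations without
#' expression data are excluded and reported.
#'
#' @param peptides Data frame \code{mutation}, \code{ic50_nM} (one row
#'   per predicted peptide).
#' @param expression Data frame \code{mutation}, \code{read_count}.
#' @param ic50_max Binding threshold (strict \code{<}).
#' @param min_reads Expression threshold (inclusive \code{>=}).
#' @return Integer count, with attribute \code{excluded} listing
#'   mutations lacking expression data.
#' @export
count_neoantigens <- function(peptides, expression, ic50_max = 500,
                              min_reads = 1) {
  muts <- unique(peptides$mutation)
  missing_expr <- setdiff(muts, expression$mutation)
  if (length(missing_expr)) {
    message(length(missing_expr),
            " mutation(s) lack expression data; excluded from neoantigen count")
  }
  binder <- tapply(peptides$ic50_nM, peptides$mutation,
                   function(v) any(v < ic50_max))
  expressed <- stats::setNames(expression$read_count >= min_reads,
                               expression$mutation)
  counted <- names(binder)[binder &
                             names(binder) %in% expression$mutation &
                             expressed[names(binder)] %in% TRUE]
  out <- length(counted)
  attr(out, "excluded") <- missing_expr
  out
}

oncokb_level_order <- c("1", "2", "3a", "3b", "4", "none")

#' Load an OncoKB-style actionability snapshot
#'
#' A versioned, packaged TSV lookup (columns \code{gene},
#' \code{alteration_type}, \code{alteration}, \code{level}) is used
#' instead of live API queries, for determinism and offline tests. The
#' packaged snapshot is a synthetic illustrative table, not OncoKB data.
#'
#' @param path Path to the snapshot TSV; default loads the packaged
#'   synthetic snapshot.
#' @return Data frame lookup table.
#' @export
read_oncokb_snapshot <- function(path = system.file(
  "extdata", "oncokb_snapshot_synthetic.tsv", package = "mutscape")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("gene", "alteration_type", "alteration", "level")
  if (!all(req %in% names(df))) stop("snapshot must have columns ",
                                     paste(req, collapse = ", "))
  if (!all(df$level %in% oncokb_level_order)) stop("unknown OncoKB level")
  df
}

#' Therapeutic-actionability classification for one sample
#'
#' Combines three axes: predicted chemotherapy responsiveness (HRD-high
#' status), the best OncoKB evidence level among the sample's
#' alterations, and the CD274 copy-number class; the neoantigen count is
#' attached when peptide/expression inputs are given.
#'
#' @param alterations Data frame of the sample's alterations:
#'   \code{gene}, \code{alteration_type} (e.g. "mutation",
#'   "amplification", "deletion", "fusion"), optional \code{alteration}
#'   (specific change; matched against the snapshot's \code{alteration}
#'   column, where \code{"any"} acts as a wildcard).
#' @param hrd HRD result list from [hrd_score()]/[classify_hrd_status()].
#' @param oncokb Snapshot table from [read_oncokb_snapshot()].
#' @param cd274_cn Total copy number of CD274 (optional).
#' @param peptides,expression Optional neoantigen inputs (see
#'   [count_neoantigens()]).
#' @return List: \code{chemo_responsive}, \code{oncokb_level},
#'   \code{cd274_class}, \code{neoantigen_count}, \code{unmatched}
#'   (alterations without a snapshot entry).
#' @export
classify_actionability <- function(alterations, hrd, oncokb = read_oncokb_snapshot(),
                                   cd274_cn = NULL, peptides = NULL,
                                   expression = NULL) {
  levels_found <- character(0)
  unmatched <- integer(0)
  if (!is.null(alterations) && nrow(alterations)) {
    if (!"alteration" %in% names(alterations)) {
      alterations$alteration <- "any"
    }
    for (i in seq_len(nrow(alterations))) {
      hit <- oncokb$gene == alterations$gene[i] &
        oncokb$alteration_type == alterations$alteration_type[i] &
        (oncokb$alteration == "any" |
           oncokb$alteration == alterations$alteration[i])
      if (any(hit)) {
        levels_found <- c(levels_found, oncokb$level[hit])
      } else {
        unmatched <- c(unmatched, i)
      }
    }
  }
  lvl <- if (length(levels_found)) {
    oncokb_level_order[min(match(levels_found, oncokb_level_order))]
  } else "none"
  list(
    chemo_responsive = hrd$status == "HRD-high",
    oncokb_level = lvl,
    cd274_class = if (!is.null(cd274_cn)) cd274_class(threshold_cn(cd274_cn))
                  else NA_character_,
    neoantigen_count = if (!is.null(peptides) && !is.null(expression))
      as.integer(count_neoantigens(peptides, expression)) else NA_integer_,
    unmatched = unmatched)
}
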