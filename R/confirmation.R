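#' Confirm a mutation by targeted amplicon resequencing
#'
#' A mutation is confirmed when its variant allele fraction in the tumor
#' amplicon data is significantly higher than in the matched control,
#' using a one-sided Fisher exact test on the alt/ref x tumor/control
#' table at a highly stringent level (default \code{alpha = 1e-9}; the
#' stricter reading \code{1e-10} can be supplied instead).
#'
#' @param alt_t,ref_t Tumor alt/ref read counts (vectors accepted).
#' @param alt_c,ref_c Control alt/ref read counts.
#' @param alpha Significance threshold.
#' @return Data frame \code{p}, \code{confirmed}.
#' @export
confirm_tas <- function(alt_t, ref_t, alt_c, ref_c, alpha = 1e-9) {
  n <- max(length(alt_t), length(ref_t), length(alt_c), length(ref_c))
  alt_t <- rep_len(alt_t, n); ref_t <- rep_len(ref_t, n)
  alt_c <- rep_len(alt_c, n); ref_c <- rep_len(ref_c, n)
  if (any(alt_t + ref_t <= 0)) stop("tumor depth must be positive")
  if (any(alt_c + ref_c <= 0)) stop("control depth must be positive")
  p <- fisher_p(alt_t, ref_t, alt_c, ref_c, alternative = "greater")
  data.frame(p = p, confirmed = p < alpha)
}

#' Summarize confirmation outcomes
#'
#' @param n_confirmed,n_input Counts of confirmed and evaluated mutations.
#' @param stratum Label for the subset evaluated (e.g. \code{">=10x"}).
#' @return One-row data frame: \code{stratum}, \code{n_input},
#'   \code{n_confirmed}, \code{rate_pct} (integer-rounded percent; NA for
#'   an empty stratum).
#' @export
confirmation_report <- function(n_confirmed, n_input, stratum = "all") {
  if (n_confirmed > n_input) stop("n_confirmed exceeds n_input")
  data.frame(stratum = stratum, n_input = as.integer(n_input),
             n_confirmed = as.integer(n_confirmed),
             rate_pct = if (n_input > 0)
               as.integer(round(100 * n_confirmed / n_input)) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' RNA-level detection of WES mutations by coverage stratum
#'
#' For each minimum RNA depth, the analysis is restricted to mutations
#' whose RNA total read count reaches that depth; a mutation is detected
#' when at least \code{min_alt} alt reads are seen.
#'
#' @param mutations Data frame with a \code{key} column identifying each
#'   WES mutation.
#' @param rna_counts Data frame \code{key}, \code{alt}, \code{total} of
#'   RNA read counts per mutation. Keys absent from \code{mutations} are
#'   reported and excluded.
#' @param min_depths Integer vector of coverage strata (0 means "all").
#' @param min_alt Alt reads required to call a mutation detected.
#' @return Data frame of per-stratum confirmation reports, with an
#'   \code{unmatched} attribute listing excluded keys.
#' @export
rna_detection <- function(mutations, rna_counts, min_depths = c(0L, 10L, 30L),
                          min_alt = 1L) {
  if (is.unsorted(min_depths)) min_depths <- sort(min_depths)
  unmatched <- setdiff(rna_counts$key, mutations$key)
  if (length(unmatched)) {
    message(length(unmatched), " RNA count record(s) unmatched to WES mutations; excluded")
  }
  rc <- rna_counts[rna_counts$key %in% mutations$key, , drop = FALSE]
  out <- do.call(rbind, lapply(min_depths, function(d) {
    sub <- rc[rc$total >= d, , drop = FALSE]
    lab <- if (d == 0) "all" else paste0(">=", d, "x")
    confirmation_report(sum(sub$alt >= min_alt), nrow(sub), stratum = lab)
  }))
  attr(out, "unmatched") <- unmatched
  out
}

#' De novo variant scan in targeted amplicon data
#'
#' For tumors without a mutation in the original WES calls, each panel
#' site is compared against a pool of all normal samples by one-sided
#' Fisher exact test; a site is called when the tumor alt fraction is
#' significantly enriched and the VAF reaches \code{vaf_min}. Calls below
#' 5\% VAF carry a low-VAF flag.
#'
#' @param tumor Data frame \code{site}, \code{alt}, \code{ref} of tumor
#'   panel counts.
#' @param pool Data frame \code{site}, \code{alt}, \code{ref} of pooled
#'   normal counts (same sites).
#' @param alpha Significance threshold.
#' @param vaf_min Minimum VAF to report a call.
#' @return Data frame of called sites: \code{site}, \code{vaf}, \code{p},
#'   \code{low_vaf}.
#' @export
denovo_tas_scan <- function(tumor, pool, alpha = 1e-9, vaf_min = 0) {
  m <- merge(tumor, pool, by = "site", suffixes = c("_t", "_p"))
  if (any(m$alt_p + m$ref_p <= 0)) stop("pooled normal depth must be positive per site")
  depth_t <- m$alt_t + m$ref_t
  keep <- depth_t > 0
  m <- m[keep, , drop = FALSE]
  p <- fisher_p(m$alt_t, m$ref_t, m$alt_p, m$ref_p, alternative = "greater")
  vaf <- m$alt_t / (m$alt_t + m$ref_t)
  called <- p < alpha & vaf >= vaf_min
  out <- data.frame(site = m$site[called], vaf = vaf[called], p = p[called],
                    stringsAsFactors = FALSE)
  out$low_vaf <- out$vaf < 0.05
  out[order(out$site), , drop = FALSE]
}
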