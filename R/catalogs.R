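#' Canonical SBS96 channel labels
#'
#' The 96 single-base-substitution channels in COSMIC ordering: the six
#' pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G),
#' each crossed with the 16 trinucleotide flanks in alphabetical order,
#' written as e.g. \code{"A[C>T]G"}.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", s, "]", three))
      }
    }
  }
  out
}

#' Canonical ID83 channel labels
#'
#' The 83 small insertion/deletion channels in COSMIC ordering:
#' 1-bp deletions/insertions of C or T by homopolymer context, longer
#' deletions/insertions (2, 3, 4, 5+ bp) by repeat-unit count, and
#' deletions at microhomology. The final field is the number of repeat
#' units flanking the event (excluding the event itself), capped at 5,
#' or the microhomology length for \code{M} channels.
#'
#' @return Character vector of length 83.
#' @export
id83_channels <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (l in c("2", "3", "4", "5")) out <- c(out, paste0(l, ":Del:R:", 0:5))
  for (l in c("2", "3", "4", "5")) out <- c(out, paste0(l, ":Ins:R:", 0:5))
  out <- c(out,
           "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  out
}

#' Read a signature catalog from TSV
#'
#' Catalogs are stored channels x signatures: first column the channel
#' label, remaining columns one signature each. Columns are renormalized
#' to sum to one and rows are reordered to the canonical channel ordering.
#'
#' @param path Path to a tab-separated catalog file.
#' @param channels Expected channel labels (defaults to SBS96 when the file
#'   has 96 rows, ID83 when it has 83).
#' @return Numeric matrix (channels x signatures) with column sums 1.
#' @export
read_catalog <- function(path, channels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  labs <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- labs
  if (is.null(channels)) {
    channels <- if (nrow(mat) == 96L) sbs96_channels()
                else if (nrow(mat) == 83L) id83_channels()
                else labs
  }
  if (!setequal(rownames(mat), channels)) {
    stop("catalog channels do not match the expected channel set")
  }
  mat <- mat[channels, , drop = FALSE]
  if (any(mat < 0)) stop("catalog contains negative entries")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("catalog contains an all-zero signature")
  sweep(mat, 2L, cs, "/")
}

#' Load the packaged synthetic SBS96 reference catalog
#'
#' A five-signature catalog (SBS1, SBS2, SBS3, SBS5, SBS13) of synthetic
#' profiles constructed to capture the qualitative character of the
#' corresponding COSMIC signatures: CpG-deamination focus for SBS1, TpC
#' APOBEC focus for SBS2/SBS13, a broad flat profile for SBS3 and a
#' clock-like profile for SBS5. These are stand-ins for testing and
#' simulation, not the COSMIC v3 estimates.
#'
#' @return 96 x 5 column-stochastic matrix.
#' @export
load_sbs_catalog <- function() {
  read_catalog(system.file("extdata", "sbs96_catalog_synthetic.tsv",
                           package = "mutscape"))
}

#' Load the packaged synthetic ID83 reference catalog
#'
#' A five-signature indel catalog (ID2, ID4, ID6, ID7, ID8) of synthetic
#' profiles: replication-slippage 1-bp T deletions for ID2, mixed repeat
#' deletions for ID4, microhomology-mediated deletions for ID6 (HRD),
#' long-homopolymer 1-bp events for ID7 (MMR) and long (5+ bp) deletions
#' for ID8. Stand-ins for testing and simulation.
#'
#' @return 83 x 5 column-stochastic matrix.
#' @export
load_id_catalog <- function() {
  read_catalog(system.file("extdata", "id83_catalog_synthetic.tsv",
                           package = "mutscape"))
}
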