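#' Genome annotation for scar scoring
#'
#' @param chrom Chromosome names.
#' @param length Chromosome lengths (bp).
#' @param cen_start,cen_end Centromere interval (bp, within bounds).
#' @return Data frame annotation used by the scar-score functions.
#' @export
genome_annotation <- function(chrom, length, cen_start, cen_end) {
  ann <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                    cen_start = as.numeric(cen_start),
                    cen_end = as.numeric(cen_end), stringsAsFactors = FALSE)
  if (any(ann$cen_start <= 0 | ann$cen_end >= ann$length |
            ann$cen_start >= ann$cen_end)) {
    stop("centromere intervals must lie strictly within chromosome bounds")
  }
  ann
}

#' Toy genome annotation for tests and simulation
#'
#' \code{n_chrom} chromosomes of 200 Mb each with a centromere at
#' 95-105 Mb.
#'
#' @param n_chrom Number of chromosomes.
#' @return Genome annotation data frame.
#' @export
toy_genome <- function(n_chrom = 3L) {
  genome_annotation(paste0("chr", seq_len(n_chrom)), rep(200e6, n_chrom),
                    rep(95e6, n_chrom), rep(105e6, n_chrom))
}

#' Load a genome annotation from TSV
#'
#' Expects columns \code{chrom}, \code{length}, \code{cen_start},
#' \code{cen_end}. The packaged \code{grch37_annotation.tsv} provides the
#' GRCh37 autosomes + X (centromere bounds rounded to the cytoband acen
#' annotation).
#'
#' @param path Path to the TSV; default loads the packaged GRCh37 file.
#' @return Genome annotation data frame.
#' @export
read_genome_annotation <- function(path = system.file(
  "extdata", "grch37_annotation.tsv", package = "mutscape")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  genome_annotation(df$chrom, df$length, df$cen_start, df$cen_end)
}

#' Read allele-specific copy-number segments (SEG-like TSV)
#'
#' Columns: \code{sample_id}, \code{chrom}, \code{start}, \code{end}
#' (1-based inclusive), \code{total_cn}, \code{minor_cn}.
#'
#' @param path File path.
#' @return Validated segment data frame.
#' @export
read_segments <- function(path) {
  validate_segments(utils::read.delim(path, stringsAsFactors = FALSE))
}

validate_segments <- function(segments) {
  req <- c("sample_id", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("missing segment columns: ", paste(miss, collapse = ", "))
  if (any(segments$end <= segments$start)) stop("segment end must exceed start")
  if (any(segments$total_cn < 0 | segments$minor_cn < 0, na.rm = TRUE)) {
    stop("negative copy numbers")
  }
  ord <- order(segments$sample_id, segments$chrom, segments$start)
  segments <- segments[ord, , drop = FALSE]
  by <- split(segments, paste(segments$sample_id, segments$chrom))
  for (b in by) {
    if (nrow(b) > 1L && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("overlapping segments within a chromosome")
    }
  }
  rownames(segments) <- NULL
  segments
}

seg_len <- function(s) s$end - s$start + 1

#' LOH scar component
#'
#' Number of loss-of-heterozygosity segments (minor copy number 0) longer
#' than \code{min_mb} megabases that do not span their whole chromosome.
#'
#' @param segments Allele-specific segments for one sample.
#' @param annotation Genome annotation covering the chromosomes present.
#' @param min_mb Minimum segment length in Mb (default 15).
#' @return Integer count.
#' @export
loh_score <- function(segments, annotation, min_mb = 15) {
  segments <- validate_segments(segments)
  if (any(is.na(segments$minor_cn))) stop("minor_cn missing")
  chrlen <- stats::setNames(annotation$length, annotation$chrom)
  frac <- seg_len(segments) / chrlen[segments$chrom]
  hit <- segments$minor_cn == 0 &
    seg_len(segments) > min_mb * 1e6 &
    frac < 1
  sum(hit)
}

#' Telomeric allelic imbalance scar component
#'
#' Number of allelic-imbalance segments (major != minor copy number) that
#' reach a telomere (touch position 1 or the chromosome end) and do not
#' cross the centromere.
#'
#' @inheritParams loh_score
#' @return Integer count.
#' @export
tai_score <- function(segments, annotation) {
  segments <- validate_segments(segments)
  missing_chr <- setdiff(unique(segments$chrom), annotation$chrom)
  if (length(missing_chr)) stop("annotation missing chromosomes: ",
                                paste(missing_chr, collapse = ", "))
  ann <- annotation[match(segments$chrom, annotation$chrom), ]
  major <- segments$total_cn - segments$minor_cn
  ai <- major != segments$minor_cn
  at_tel <- segments$start <= 1 | segments$end >= ann$length
  crosses_cen <- segments$start <= ann$cen_end & segments$end >= ann$cen_start
  whole <- segments$start <= 1 & segments$end >= ann$length
  sum(ai & at_tel & !crosses_cen & !whole)
}

#' Large-scale state transition scar component
#'
#' Segments are assigned to chromosome arms (split at the centromere
#' midpoint), segments shorter than \code{smooth_mb} are removed,
#' equal-copy-number neighbors are merged, and each breakpoint between
#' adjacent segments both at least \code{min_mb} long with an
#' inter-segment gap under \code{smooth_mb} counts one transition.
#'
#' @inheritParams loh_score
#' @param min_mb Minimum length of both flanking segments (Mb).
#' @param smooth_mb Filtering/merging scale (Mb): segments shorter than
#'   this are dropped and larger gaps break adjacency.
#' @return Integer count.
#' @export
lst_score <- function(segments, annotation, min_mb = 10, smooth_mb = 3) {
  segments <- validate_segments(segments)
  ann <- annotation[match(segments$chrom, annotation$chrom), ]
  if (any(is.na(ann$chrom))) stop("annotation missing chromosomes")
  cen_mid <- (ann$cen_start + ann$cen_end) / 2
  # split segments crossing the centromere midpoint into arm-wise pieces
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    mid <- cen_mid[i]
    if (s$start < mid && s$end > mid) {
      p1 <- s; p1$end <- floor(mid); p1$arm <- "p"
      q1 <- s; q1$start <- floor(mid) + 1; q1$arm <- "q"
      pieces[[length(pieces) + 1L]] <- p1
      pieces[[length(pieces) + 1L]] <- q1
    } else {
      s$arm <- if (s$end <= mid) "p" else "q"
      pieces[[length(pieces) + 1L]] <- s
    }
  }
  segs <- do.call(rbind, pieces)
  total <- 0L
  for (key in unique(paste(segs$chrom, segs$arm))) {
    b <- segs[paste(segs$chrom, segs$arm) == key, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    b <- b[seg_len(b) >= smooth_mb * 1e6, , drop = FALSE]
    if (nrow(b) < 2L) next
    # merge equal-CN neighbors
    merged <- b[1, , drop = FALSE]
    for (i in 2:nrow(b)) {
      last <- nrow(merged)
      if (b$total_cn[i] == merged$total_cn[last] &&
          b$minor_cn[i] == merged$minor_cn[last]) {
        merged$end[last] <- b$end[i]
      } else {
        merged <- rbind(merged, b[i, , drop = FALSE])
      }
    }
    if (nrow(merged) < 2L) next
    for (i in 2:nrow(merged)) {
      gap <- merged$start[i] - merged$end[i - 1] - 1
      if (gap < smooth_mb * 1e6 &&
          seg_len(merged[i - 1, ]) >= min_mb * 1e6 &&
          seg_len(merged[i, ]) >= min_mb * 1e6) {
        total <- total + 1L
      }
    }
  }
  total
}

#' HRD scar score and status
#'
#' The HRD score is the sum of the LOH, TAI and LST components. A tumor
#' is HRD-high when the score reaches \code{cutoff} (default 42,
#' inclusive) or when it carries a pathogenic germline or somatic BRCA1/2
#' alteration, which overrides the score.
#'
#' @param segments Allele-specific segments for one sample.
#' @param annotation Genome annotation.
#' @param brca_flag Logical: any pathogenic BRCA1/BRCA2 alteration.
#' @param cutoff HRD-high score threshold (inclusive).
#' @return List: \code{loh}, \code{tai}, \code{lst}, \code{score},
#'   \code{status} ("HRD-high"/"HRD-low"), \code{brca_override}.
#' @export
hrd_score <- function(segments, annotation, brca_flag = FALSE, cutoff = 42) {
  loh <- loh_score(segments, annotation)
  tai <- tai_score(segments, annotation)
  lst <- lst_score(segments, annotation)
  classify_hrd_status(loh, tai, lst, brca_flag = brca_flag, cutoff = cutoff)
}

#' @rdname hrd_score
#' @param loh,tai,lst Precomputed scar components.
#' @export
classify_hrd_status <- function(loh, tai, lst, brca_flag = FALSE, cutoff = 42) {
  score <- loh + tai + lst
  override <- isTRUE(brca_flag) && score < cutoff
  status <- if (score >= cutoff || isTRUE(brca_flag)) "HRD-high" else "HRD-low"
  list(loh = as.integer(loh), tai = as.integer(tai), lst = as.integer(lst),
       score = as.integer(score), status = status, brca_override = override)
}
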