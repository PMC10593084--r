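#' Reciprocal overlap between genomic intervals
#'
#' The symmetric similarity used throughout structural-variant matching:
#' `min(overlap / length(a), overlap / length(b))`. Intervals are 0-based
#' half-open, the package-internal convention; the fraction is 0 when the
#' intervals do not intersect or lie on different chromosomes.
#'
#' @param start1,end1 Numeric vectors, first interval (0-based half-open).
#' @param start2,end2 Numeric vectors, second interval.
#' @param chrom1,chrom2 Optional chromosome names; when both are supplied a
#'   chromosome mismatch forces the fraction to 0.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' reciprocal_overlap(0, 100, 50, 150)  # 0.5
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  if (any(start1 >= end1) || any(start2 >= end2)) {
    rlang::abort("invalid interval: start must be < end")
  }
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  ro <- pmin(ov / (end1 - start1), ov / (end2 - start2))
  if (!is.null(chrom1) && !is.null(chrom2)) {
    ro[norm_chrom(chrom1) != norm_chrom(chrom2)] <- 0
  }
  ro
}

#' Normalize chromosome names to the "chr"-prefixed dialect
#'
#' @param chrom Character vector of chromosome names ("1", "chr1", "X", ...).
#' @param prefix Dialect to emit; `"chr"` (default) or `""` for the bare form.
#' @return Character vector in the requested dialect.
#' @export
norm_chrom <- function(chrom, prefix = "chr") {
  bare <- sub("^chr", "", as.character(chrom))
  paste0(prefix, bare)
}

#' @keywords internal
is_autosome <- function(chrom) {
  grepl("^[0-9]+$", sub("^chr", "", as.character(chrom)))
}

#' Count array probes falling inside an interval
#'
#' Probes are treated as point assays located at their BED start; a probe is
#' inside `[start, end)` when `start <= pos < end`. Duplicate positions on a
#' chromosome count once. Implemented with binary search over the sorted
#' probe table.
#'
#' @param chrom,start,end The query interval (0-based half-open).
#' @param probes Probe tibble with columns `chrom`, `start` (see
#'   [read_probes()]).
#' @return Non-negative integer count.
#' @export
count_overlapping_probes <- function(chrom, start, end, probes) {
  pos <- sort(unique(probes$start[norm_chrom(probes$chrom) == norm_chrom(chrom)]))
  if (length(pos) == 0L) return(0L)
  # findInterval gives, for x, the number of positions <= x
  n_below_end <- findInterval(end - 1, pos)
  n_below_start <- findInterval(start - 1, pos)
  as.integer(n_below_end - n_below_start)
}

#' Exons of a transcript overlapped by an interval
#'
#' @param chrom,start,end Query interval (0-based half-open).
#' @param transcript Exon-level tibble for one transcript: columns `chrom`,
#'   `exon_start`, `exon_end`, one row per exon sorted by start.
#' @return List with `count` (integer) and `indices` (positions of overlapped
#'   exons in transcript order).
#' @export
exons_overlapped <- function(chrom, start, end, transcript) {
  tx <- dplyr::arrange(transcript, .data$exon_start)
  hit <- norm_chrom(tx$chrom) == norm_chrom(chrom) &
    tx$exon_start < end & tx$exon_end > start
  list(count = sum(hit), indices = which(hit))
}

#' Overlap join between an event/interval table and a feature table
#'
#' Internal helper: returns pairs (row index of x, row index of y) with >= 1 bp
#' overlap on the same (normalized) chromosome.
#' @keywords internal
interval_overlap_pairs <- function(x, y,
                                   x_start = "start", x_end = "end",
                                   y_start = "start", y_end = "end") {
  gx <- GenomicRanges::GRanges(norm_chrom(x$chrom),
                               IRanges::IRanges(x[[x_start]] + 1, x[[x_end]]))
  gy <- GenomicRanges::GRanges(norm_chrom(y$chrom),
                               IRanges::IRanges(y[[y_start]] + 1, y[[y_end]]))
  hits <- GenomicRanges::findOverlaps(gx, gy)
  tibble::tibble(x = S4Vectors::queryHits(hits), y = S4Vectors::subjectHits(hits))
}

#' Same-allele reciprocal-overlap threshold for a pair of SVs
#'
#' Large SVs (> 5 kb) must share 50% reciprocal overlap to be treated as the
#' same allele; smaller SVs need only 10%. A pair mixing size classes uses the
#' permissive 10% threshold.
#' @param len1,len2 Lengths in bp of the two SVs.
#' @param large_min_bp Size (bp) above which an SV counts as "large" (5000).
#' @param ro_large,ro_small The two thresholds (0.50, 0.10).
#' @return Numeric vector of thresholds.
#' @export
same_allele_threshold <- function(len1, len2, large_min_bp = 5000,
                                  ro_large = 0.50, ro_small = 0.10) {
  ifelse(len1 > large_min_bp & len2 > large_min_bp, ro_large, ro_small)
}
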