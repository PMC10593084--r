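#' Quality-score thresholds for the caller's gates
#'
#' The per-type gates applied to read-depth CNV calls: duplications pass at
#' QS >= 50, heterozygous deletions at QS >= 100, homozygous deletions at
#' QS >= 400; a looser per-analysis screen uses QS >= 50 for everything.
#' Comparisons use greater-or-equal semantics.
#'
#' @param dup_min,del_min,homdel_min,analysis_min Gate values.
#' @return A `qs_thresholds` list.
#' @export
qs_thresholds <- function(dup_min = 50, del_min = 100, homdel_min = 400,
                          analysis_min = 50) {
  stopifnot(homdel_min >= del_min, del_min >= analysis_min)
  structure(list(dup_min = dup_min, del_min = del_min,
                 homdel_min = homdel_min, analysis_min = analysis_min),
            class = "qs_thresholds")
}

#' Mode-of-inheritance frequency limits
#'
#' Dominant analyses keep calls with in-cohort frequency < 0.1%; recessive
#' analyses use < 1%. Comparisons are strict.
#' @param dominant_max,recessive_max Limits as fractions.
#' @return A `moi_limits` list.
#' @export
moi_limits <- function(dominant_max = 0.001, recessive_max = 0.01) {
  stopifnot(dominant_max < recessive_max)
  structure(list(dominant_max = dominant_max, recessive_max = recessive_max),
            class = "moi_limits")
}

#' Per-type quality-score gate
#'
#' @param calls Call tibble.
#' @param thresholds A [qs_thresholds()] object.
#' @return Logical vector, one element per call.
#' @export
passes_qs_gate <- function(calls, thresholds = qs_thresholds()) {
  gate <- dplyr::case_when(
    calls$svtype == "DUP" ~ thresholds$dup_min,
    calls$svtype == "DEL" & calls$cn == 0 ~ thresholds$homdel_min,
    calls$svtype == "DEL" ~ thresholds$del_min,
    TRUE ~ thresholds$analysis_min
  )
  calls$qs >= gate
}

#' High-confidence call flag
#'
#' A call is high-confidence when all four criteria hold: (1) it comes from a
#' high-quality sample (see [sample_qc()]); (2) its same-allele cluster
#' frequency is <= 0.01; (3) it overlaps at least 3 exons; (4) it passes the
#' per-type QS gate.
#'
#' @param calls Call tibble with `frequency` (from [cluster_alleles()]) and
#'   `n_exons` (from [annotate_exon_counts()]) filled in.
#' @param qc Per-sample QC tibble from [sample_qc()].
#' @param thresholds A [qs_thresholds()] object.
#' @param max_frequency Frequency ceiling (0.01).
#' @param min_exons Minimum overlapped exons (3).
#' @return `calls` with a logical `high_confidence` column added.
#' @export
flag_high_confidence <- function(calls, qc, thresholds = qs_thresholds(),
                                 max_frequency = 0.01, min_exons = 3) {
  if (any(is.na(calls$n_exons))) {
    rlang::abort("n_exons missing: annotate exon counts first")
  }
  if (!"frequency" %in% names(calls) || any(is.na(calls$frequency))) {
    rlang::abort("frequency missing: run cluster_alleles() first")
  }
  hq <- stats::setNames(qc$is_high_quality, qc$sample_id)
  dplyr::mutate(calls, high_confidence =
                  unname(hq[.data$sample_id]) &
                  .data$frequency <= max_frequency &
                  .data$n_exons >= min_exons &
                  passes_qs_gate(calls, thresholds))
}

#' Mode-of-inheritance frequency filter
#'
#' Retains calls whose in-cohort allele frequency is strictly below the limit
#' for the requested mode of inheritance (< 0.1% dominant, < 1% recessive).
#' The `allele_frequency` column from [cluster_alleles()] is used when
#' present; otherwise the carrier `frequency` stands in.
#' @param calls Call tibble with a frequency column.
#' @param moi `"dominant"` or `"recessive"`.
#' @param limits A [moi_limits()] object.
#' @return Filtered call tibble.
#' @export
filter_by_moi <- function(calls, moi = c("dominant", "recessive"),
                          limits = moi_limits()) {
  moi <- match.arg(moi)
  lim <- if (moi == "dominant") limits$dominant_max else limits$recessive_max
  f <- if ("allele_frequency" %in% names(calls)) calls$allele_frequency
       else calls$frequency
  calls[f < lim, ]
}
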