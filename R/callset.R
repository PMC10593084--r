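#' Cluster calls into same-allele groups and compute frequencies
#'
#' Single-linkage clustering of segment calls: two calls link when they share
#' the SV type and their reciprocal overlap reaches the size-dependent
#' same-allele threshold (50% when both calls exceed 5 kb, 10% otherwise; see
#' [same_allele_threshold()]). Two frequencies are reported per cluster:
#' `frequency`, the carrier (sample) fraction used by the high-confidence
#' flag, and `allele_frequency`, used by the mode-of-inheritance filters.
#' Allele counts per carrier are `2 - cn` (capped to 1..2) for deletions,
#' 1 for duplications (multi-allelic gains are not resolvable from a copy
#' number alone), and 1 for hemizygous sex-chromosome calls in males when a
#' pedigree is supplied; the denominator is `2 * n_samples`.
#'
#' Candidate pairs are found with an interval overlap query and connected
#' components are taken over the resulting link graph, which equals the
#' transitive closure of the pairwise rule.
#'
#' @param calls Call tibble (see [read_segments()]).
#' @param n_samples Number of samples in the callset (frequency denominator);
#'   defaults to the number of distinct `sample_id`s present.
#' @param ped Optional pedigree tibble ([read_ped()]) used to count one
#'   allele for male sex-chromosome calls.
#' @return `calls` with `cluster_id`, `frequency` and `allele_frequency`
#'   columns added.
#' @export
cluster_alleles <- function(calls,
                            n_samples = dplyr::n_distinct(calls$sample_id),
                            ped = NULL) {
  calls <- calls[, setdiff(names(calls), c("cluster_id", "frequency",
                                           "allele_frequency"))]
  n <- nrow(calls)
  if (n == 0) {
    return(dplyr::mutate(calls, cluster_id = integer(), frequency = numeric(),
                         allele_frequency = numeric()))
  }
  pairs <- interval_overlap_pairs(calls, calls)
  pairs <- pairs[pairs$x < pairs$y &
                   calls$svtype[pairs$x] == calls$svtype[pairs$y], ]
  if (nrow(pairs) > 0) {
    ro <- reciprocal_overlap(calls$start[pairs$x], calls$end[pairs$x],
                             calls$start[pairs$y], calls$end[pairs$y])
    thr <- same_allele_threshold(calls$end[pairs$x] - calls$start[pairs$x],
                                 calls$end[pairs$y] - calls$start[pairs$y])
    pairs <- pairs[ro >= thr, ]
  }
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  out <- dplyr::mutate(calls, cluster_id = as.integer(comp))
  males <- if (!is.null(ped)) ped$sample_id[ped$sex == "M"] else character()
  ac <- ifelse(!is_autosome(out$chrom) & out$sample_id %in% males, 1,
               ifelse(out$svtype == "DEL", pmin(2, pmax(1, 2 - out$cn)), 1))
  freq <- out |>
    dplyr::mutate(.ac = ac) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      frequency = dplyr::n_distinct(.data$sample_id) / n_samples,
      allele_frequency = sum(.data$.ac) / (2 * n_samples),
      .groups = "drop")
  dplyr::left_join(out, freq, by = "cluster_id")
}

#' Per-sample quality control over raw calls
#'
#' A sample is high quality when it has at most 200 raw autosomal CNV calls
#' of which at least 35 have QS > 20. Counts are taken over the raw
#' (unfiltered) callset; sex-chromosome calls are excluded from both counts.
#'
#' @param calls Call tibble over all raw calls.
#' @param max_autosomal_calls Maximum raw autosomal call count (200).
#' @param min_qs20_calls Minimum number of autosomal calls with QS > 20 (35).
#' @return Tibble `sample_id`, `n_autosomal_raw_calls`, `n_calls_qs_gt20`,
#'   `is_high_quality`.
#' @export
sample_qc <- function(calls, max_autosomal_calls = 200, min_qs20_calls = 35) {
  calls |>
    dplyr::filter(is_autosome(.data$chrom)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_autosomal_raw_calls = dplyr::n(),
                     n_calls_qs_gt20 = sum(.data$qs > 20),
                     .groups = "drop") |>
    dplyr::bind_rows(
      tibble::tibble(sample_id = setdiff(unique(calls$sample_id),
                                         calls$sample_id[is_autosome(calls$chrom)]),
                     n_autosomal_raw_calls = 0L, n_calls_qs_gt20 = 0L)
    ) |>
    dplyr::mutate(is_high_quality =
                    .data$n_autosomal_raw_calls <= max_autosomal_calls &
                    .data$n_calls_qs_gt20 >= min_qs20_calls) |>
    dplyr::arrange(.data$sample_id)
}
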