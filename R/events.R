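#' Assemble per-sample calls into events, merging fragmented large CNVs
#'
#' Large read-depth CNVs are often emitted as several smaller calls. Calls
#' from the same sample, chromosome and SV type whose gap is at most
#' `max_gap_bp` are merged into one event, unless a call of the opposite type
#' overlaps the gap between them (an opposite-direction signal argues against
#' a single underlying event). The merge is transitive and independent of
#' input order; each unmerged call becomes a single-component event.
#'
#' @param calls Call tibble for one or more samples.
#' @param max_gap_bp Maximum gap bridged by a merge (default 1 Mb).
#' @param same_type_only Merge only same-SVTYPE calls (default TRUE; FALSE is
#'   for exploratory reassembly only).
#' @return Event tibble: `event_id`, `sample_id`, `chrom`, `start`, `end`
#'   (union span), `resolved_type`, `inheritance` ("unknown"),
#'   `n_components`, `qs` (max over components), `score` (max over an
#'   optional per-call `score` column, else NA), `cn` (component consensus
#'   or NA), `components` (list column of call tibbles).
#' @export
merge_fragments <- function(calls, max_gap_bp = 1e6, same_type_only = TRUE) {
  if (nrow(calls) == 0) return(empty_events())
  calls <- dplyr::mutate(calls, .row = dplyr::row_number())
  key <- if (same_type_only) c("sample_id", "chrom", "svtype")
         else c("sample_id", "chrom")
  groups <- dplyr::group_split(dplyr::group_by(calls, dplyr::across(
    dplyr::all_of(key))))
  events <- purrr::map_dfr(groups, function(g) {
    g <- dplyr::arrange(g, .data$start, .data$end)
    blockers <- calls[calls$sample_id == g$sample_id[1] &
                        norm_chrom(calls$chrom) == norm_chrom(g$chrom[1]) &
                        calls$svtype != g$svtype[1], ]
    comp <- integer(nrow(g))
    comp[1] <- 1L
    cur_end <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      gap_ok <- g$start[i] - cur_end <= max_gap_bp
      blocked <- same_type_only && nrow(blockers) > 0 &&
        any(blockers$start < g$start[i] & blockers$end > cur_end)
      comp[i] <- if (gap_ok && !blocked) comp[i - 1] else comp[i - 1] + 1L
      cur_end <- max(cur_end, g$end[i])
      if (comp[i] != comp[i - 1]) cur_end <- g$end[i]
    }
    g |>
      dplyr::mutate(.block = comp) |>
      dplyr::group_by(.data$.block) |>
      dplyr::summarise(
        sample_id = .data$sample_id[1],
        chrom = .data$chrom[1],
        start = min(.data$start),
        end = max(.data$end),
        resolved_type = .data$svtype[1],
        n_components = dplyr::n(),
        qs = max(.data$qs),
        # ingested deleteriousness scores: a fragmented event falls back to
        # the max over its components unless a span-level score is supplied
        score = if ("score" %in% names(calls)) max(.data$score)
                else NA_real_,
        cn = if (dplyr::n_distinct(.data$cn) == 1) .data$cn[1] else NA_real_,
        components = list(dplyr::pick(dplyr::everything())[
          , setdiff(names(calls), c(".row", ".block"))]),
        .groups = "drop") |>
      dplyr::select(-".block")
  })
  events |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start) |>
    dplyr::mutate(event_id = sprintf("ev%04d", dplyr::row_number()),
                  inheritance = "unknown") |>
    dplyr::relocate("event_id")
}

#' @keywords internal
empty_events <- function() {
  tibble::tibble(event_id = character(), sample_id = character(),
                 chrom = character(), start = numeric(), end = numeric(),
                 resolved_type = character(), inheritance = character(),
                 n_components = integer(), qs = numeric(), score = numeric(),
                 cn = numeric(), components = list())
}

#' Flag candidate complex structural variants
#'
#' A complex SV is a rearrangement with three or more breakpoint junctions
#' that cannot be described as a single canonical SV type. On read-depth data
#' it typically appears as clustered events of discordant type (del/dup) or
#' as a paired-duplication pattern flanking a gap. Within one sample and
#' chromosome, any pair of events separated by at most `window_bp` is jointly
#' flagged `SUSPECTED_CPX` when the two types differ, or when both are
#' duplications flanking a non-empty gap.
#'
#' @param events Event tibble from [merge_fragments()].
#' @param window_bp Clustering window (default 2 Mb).
#' @return `events` with `resolved_type` set to `"SUSPECTED_CPX"` on flagged
#'   rows and the original type kept in `component_type`.
#' @export
flag_complex_candidate <- function(events, window_bp = 2e6) {
  events$component_type <- events$resolved_type
  if (nrow(events) < 2) return(events)
  flagged <- rep(FALSE, nrow(events))
  idx <- split(seq_len(nrow(events)),
               paste(events$sample_id, norm_chrom(events$chrom)))
  for (ii in idx) {
    if (length(ii) < 2) next
    for (a in ii) for (b in ii) {
      if (a >= b) next
      gap <- max(events$start[a], events$start[b]) -
        min(events$end[a], events$end[b])
      if (gap > window_bp) next
      differing <- events$component_type[a] != events$component_type[b]
      paired_dup <- events$component_type[a] == "DUP" &&
        events$component_type[b] == "DUP" && gap > 0
      if (differing || paired_dup) flagged[c(a, b)] <- TRUE
    }
  }
  events$resolved_type[flagged] <- "SUSPECTED_CPX"
  events
}

#' Resolve event types with orthogonal validation evidence
#'
#' Validation records (FISH, karyotype, CMA, MLPA, Sanger, qPCR, ddPCR,
#' genome sequencing, long-range PCR) can correct the type called from read
#' depth — e.g. a mobile-element insertion miscalled as a deletion — and
#' refine breakpoints. The record's `resolved_type` replaces the event's;
#' refined breakpoints are adopted when present; provenance is retained in
#' `validation_method`.
#'
#' @param events Event tibble.
#' @param validation Tibble with `event_id`, `method`, `resolved_type`, and
#'   optional refined `chrom`, `start`, `end`, `notes`.
#' @return Updated event tibble.
#' @export
resolve_with_validation <- function(events, validation) {
  valid_methods <- c("FISH", "karyotype", "CMA", "MLPA", "Sanger", "qPCR",
                     "ddPCR", "genome_short", "genome_long", "long_range_PCR")
  if (!all(validation$method %in% valid_methods)) {
    rlang::abort("unknown validation method")
  }
  if (!"validation_method" %in% names(events)) {
    events$validation_method <- NA_character_
  }
  for (i in seq_len(nrow(validation))) {
    v <- validation[i, ]
    j <- match(v$event_id, events$event_id)
    if (is.na(j)) rlang::abort(paste0("no such event: ", v$event_id))
    if (!is.null(v$chrom) && !is.na(v$chrom)) {
      if (norm_chrom(v$chrom) != norm_chrom(events$chrom[j])) {
        rlang::abort("validation chromosome does not match event")
      }
      if (!is.na(v$start) && !is.na(v$end)) {
        if (v$start >= v$end) rlang::abort("invalid validation breakpoints")
        events$start[j] <- v$start
        events$end[j] <- v$end
      }
    }
    events$resolved_type[j] <- v$resolved_type
    events$validation_method[j] <- v$method
  }
  events
}
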