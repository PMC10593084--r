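#' Fill the overlapped-exon count on calls
#'
#' Counts distinct gene-model exons with >= 1 bp overlap per call, the
#' quantity the high-confidence flag thresholds at 3.
#'
#' @param calls Call tibble.
#' @param gene_model Exon-level gene model tibble (see [read_gene_model()]).
#' @return `calls` with `n_exons` filled (0 where nothing overlaps).
#' @export
annotate_exon_counts <- function(calls, gene_model) {
  if (nrow(calls) == 0) return(calls)
  pairs <- interval_overlap_pairs(calls, gene_model,
                                  y_start = "exon_start", y_end = "exon_end")
  counts <- tibble::tibble(call = pairs$x) |>
    dplyr::count(.data$call, name = "n")
  calls$n_exons <- 0
  calls$n_exons[counts$call] <- counts$n
  calls
}

#' Annotate events with gene content across one or more gene models
#'
#' For each event, counts overlapping protein-coding genes per annotation
#' source, flags source disagreement, determines whether the event is
#' intragenic (both endpoints inside the span of the single overlapped gene),
#' computes per-gene overlapped-exon counts, and attaches dosage/disease-gene
#' records.
#'
#' Gene-count sources routinely disagree; the count used for scoring
#' (`n_genes`) defaults to the most conservative (smallest) source, and can
#' be pinned to a named source instead.
#'
#' @param events Event tibble.
#' @param gene_models Exon-level gene model tibble; multiple sources are
#'   distinguished by `source_label`.
#' @param dosage Optional dosage table (see [read_dosage()]).
#' @param count_source `"conservative"` (default: per-event minimum across
#'   sources) or a `source_label` present in `gene_models`.
#' @return `events` with columns `gene_counts` (named list column, count per
#'   source), `n_genes`, `discordant_sources`, `genes` (list column of
#'   overlapped protein-coding gene ids), `intragenic`, `exon_counts` (named
#'   list column per gene), `disease_genes` (list column of dosage rows).
#' @export
annotate_gene_content <- function(events, gene_models, dosage = NULL,
                                  count_source = "conservative") {
  if (nrow(gene_models) == 0) rlang::abort("empty gene model")
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, gene_counts = list(),
                         discordant_sources = logical(),
                         n_genes = integer(), genes = list(),
                         intragenic = logical(), exon_counts = list(),
                         disease_genes = list()))
  }
  sources <- unique(gene_models$source_label)
  if (count_source != "conservative" && !count_source %in% sources) {
    rlang::abort(paste0("unknown gene-model source: ", count_source))
  }
  per_gene <- gene_models |>
    dplyr::group_by(.data$source_label, .data$gene_id, .data$biotype) |>
    dplyr::summarise(chrom = .data$chrom[1],
                     gene_start = min(.data$exon_start),
                     gene_end = max(.data$exon_end), .groups = "drop")
  pairs <- interval_overlap_pairs(events, per_gene,
                                  y_start = "gene_start", y_end = "gene_end")
  hit <- dplyr::bind_cols(tibble::tibble(event = pairs$x), per_gene[pairs$y, ])
  pc_hit <- hit[hit$biotype == "protein_coding", ]
  out <- events
  out$gene_counts <- purrr::map(seq_len(nrow(events)), function(i) {
    h <- pc_hit[pc_hit$event == i, ]
    vapply(sources, function(s) sum(h$source_label == s), integer(1))
  })
  out$discordant_sources <- purrr::map_lgl(out$gene_counts,
                                           ~ length(unique(.x)) > 1)
  out$n_genes <- purrr::map_int(out$gene_counts, function(gc) {
    if (count_source == "conservative") min(gc) else gc[[count_source]]
  })
  ref_source <- if (count_source == "conservative") sources[1] else count_source
  out$genes <- purrr::map(seq_len(nrow(events)), function(i) {
    unique(pc_hit$gene_id[pc_hit$event == i & pc_hit$source_label == ref_source])
  })
  out$intragenic <- purrr::map_lgl(seq_len(nrow(events)), function(i) {
    h <- hit[hit$event == i & hit$source_label == ref_source, ]
    nrow(h) == 1 && events$start[i] >= h$gene_start && events$end[i] <= h$gene_end
  })
  ref_gm <- gene_models[gene_models$source_label == ref_source, ]
  out$exon_counts <- purrr::map(seq_len(nrow(events)), function(i) {
    gs <- out$genes[[i]]
    vapply(gs, function(g) {
      exons_overlapped(events$chrom[i], events$start[i], events$end[i],
                       dplyr::rename(ref_gm[ref_gm$gene_id == g, ],
                                     chrom2 = "chrom") |>
                         dplyr::rename(chrom = "chrom2"))$count
    }, integer(1))
  })
  out$disease_genes <- purrr::map(out$genes, function(gs) {
    if (is.null(dosage)) return(tibble::tibble())
    dosage[dosage$gene %in% gs, ]
  })
  out
}

#' Match events against a population SV panel
#'
#' An event matches a panel SV (same-allele rule) when the types agree and
#' the reciprocal overlap reaches the size-dependent threshold: 50% when both
#' exceed 5 kb, 10% otherwise.
#'
#' @param events Event tibble.
#' @param panel Population panel tibble (see [read_panel()]).
#' @return `events` with `pop_n_matches`, `pop_max_af` (0 when unmatched).
#' @export
match_population_sv <- function(events, panel) {
  events$pop_n_matches <- 0L
  events$pop_max_af <- 0
  if (nrow(events) == 0 || nrow(panel) == 0) return(events)
  pairs <- interval_overlap_pairs(events, panel)
  if (nrow(pairs) == 0) return(events)
  keep <- events$resolved_type[pairs$x] == panel$svtype[pairs$y]
  pairs <- pairs[keep, ]
  ro <- reciprocal_overlap(events$start[pairs$x], events$end[pairs$x],
                           panel$start[pairs$y], panel$end[pairs$y])
  thr <- same_allele_threshold(events$end[pairs$x] - events$start[pairs$x],
                               panel$end[pairs$y] - panel$start[pairs$y])
  pairs <- pairs[ro >= thr, ]
  if (nrow(pairs) == 0) return(events)
  agg <- tibble::tibble(event = pairs$x, af = panel$af[pairs$y]) |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(n = dplyr::n(), max_af = max(.data$af), .groups = "drop")
  events$pop_n_matches[agg$event] <- agg$n
  events$pop_max_af[agg$event] <- agg$max_af
  events
}

#' Microarray detectability of events
#'
#' An event is confidently detectable by a chromosomal microarray when at
#' least `min_probes` array probes fall within its span (probes are point
#' assays at their start position). Complex events are assessed on the union
#' span.
#'
#' @param events Event tibble.
#' @param probes Probe tibble (see [read_probes()]).
#' @param min_probes Minimum probe count for detectability (5).
#' @return `events` with `n_probes` and logical `cma_detectable` columns.
#' @export
cma_detectable <- function(events, probes, min_probes = 5) {
  events$n_probes <- vapply(seq_len(nrow(events)), function(i) {
    count_overlapping_probes(events$chrom[i], events$start[i], events$end[i],
                             probes)
  }, integer(1))
  events$cma_detectable <- events$n_probes >= min_probes
  events
}

#' Classifier-threshold metrics for a deleteriousness score
#'
#' Evaluates an ingested in-silico score (e.g. a 0-1 deleteriousness
#' predictor) at a cutoff: true-positive rate among causal records,
#' false-positive rate among non-causal records (both with the strict `>`
#' comparison used for such scores), and the per-class medians.
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param causal Logical vector, same length.
#' @param cutoff Score cutoff (default 0.37).
#' @return One-row tibble: `cutoff`, `tpr`, `fpr`, `median_causal`,
#'   `median_noncausal`; medians are `NA` for an empty class.
#' @export
threshold_metrics <- function(scores, causal, cutoff = 0.37) {
  stopifnot(length(scores) == length(causal))
  pos <- scores[causal]
  neg <- scores[!causal]
  tibble::tibble(
    cutoff = cutoff,
    tpr = if (length(pos)) mean(pos > cutoff) else NA_real_,
    fpr = if (length(neg)) mean(neg > cutoff) else NA_real_,
    median_causal = if (length(pos)) stats::median(pos) else NA_real_,
    median_noncausal = if (length(neg)) stats::median(neg) else NA_real_
  )
}
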