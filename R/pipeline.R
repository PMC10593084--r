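#' Classify annotated events with the point engine
#'
#' Assembles evidence items per event and aggregates them into a five-tier
#' classification. Per event the engine considers, in order:
#'
#' * Category-2 dosage evidence for the first established disease gene
#'   overlapped: complete removal (or gain) of an established
#'   haploinsufficient (triplosensitive) gene under autosomal-dominant
#'   inheritance scores the established-region points; otherwise
#'   loss-of-function eligibility is evaluated with the PVS1-style decision
#'   tree ([pvs1_strength()]) and scored as category 2E.
#' * Gene-number (section-3) evidence for canonical deletions/duplications.
#' * Case evidence routed by the established gene's mode of inheritance:
#'   the PM3-style autosomal-recessive table, the X-linked case table, or de
#'   novo occurrence plus the once-per-variant phenotype bonus for dominant
#'   conditions.
#' * Functional evidence at the strongest level observed.
#'
#' Complex events (`CPX`/`SUSPECTED_CPX`) with multiple components are
#' classified per component and default to the most deleterious component
#' classification.
#'
#' Observations are matched to events by `sample_id`, and — when the
#' observation names a `gene` — by that gene being overlapped by the event.
#'
#' @param events Event tibble; annotated with [annotate_gene_content()]
#'   first (done on the fly when the columns are missing).
#' @param gene_models Exon-level gene model tibble.
#' @param dosage Dosage table.
#' @param observations Case-observation tibble (may be NULL).
#' @param scheme A [scoring_scheme()].
#' @param count_source Gene-count source policy (see
#'   [annotate_gene_content()]).
#' @return `events` with `total`, `classification` and a `result` list column
#'   of `cnv_classification` objects.
#' @export
classify_events <- function(events, gene_models, dosage = NULL,
                            observations = NULL, scheme = scoring_scheme(),
                            count_source = "conservative") {
  if (!"n_genes" %in% names(events)) {
    events <- annotate_gene_content(events, gene_models, dosage, count_source)
  }
  src_rows <- table(gene_models$source_label)
  ref_gm <- gene_models[gene_models$source_label ==
                          names(src_rows)[which.max(src_rows)], ]
  results <- purrr::map(seq_len(nrow(events)), function(i) {
    classify_one(events[i, ], ref_gm, gene_models, dosage, observations,
                 scheme, count_source)
  })
  events$result <- results
  events$total <- vapply(results, function(r) r$total, numeric(1))
  events$classification <- vapply(results, function(r) r$classification,
                                  character(1))
  events
}

#' @keywords internal
match_observations <- function(ev, observations) {
  if (is.null(observations) || nrow(observations) == 0) return(NULL)
  obs <- observations[observations$sample_id == ev$sample_id, ]
  if (nrow(obs) == 0) return(NULL)
  if ("gene" %in% names(obs)) {
    genes <- ev$genes[[1]]
    obs <- obs[is.na(obs$gene) | obs$gene %in% genes, ]
  }
  if (nrow(obs) == 0) NULL else obs
}

#' @keywords internal
classify_one <- function(ev, ref_gm, gene_models, dosage, observations,
                         scheme, count_source) {
  if (ev$resolved_type %in% c("CPX", "SUSPECTED_CPX") &&
      ev$n_components > 1) {
    comps <- ev$components[[1]]
    comp_events <- merge_fragments(comps, max_gap_bp = 0)
    comp_events <- annotate_gene_content(comp_events, gene_models, dosage,
                                         count_source)
    comp_results <- purrr::map(seq_len(nrow(comp_events)), function(j) {
      classify_one(comp_events[j, ], ref_gm, gene_models, dosage,
                   observations, scheme, count_source)
    })
    return(classify_complex(comp_results, event_id = ev$event_id))
  }
  obs <- match_observations(ev, observations)
  items <- empty_evidence()
  dg <- ev$disease_genes[[1]]
  dg <- if (!is.null(dg) && nrow(dg) > 0) dg[dg$established, ] else dg
  moi <- NA_character_
  if (!is.null(dg) && nrow(dg) > 0) {
    dg <- dg[1, ]
    moi <- dg$moi
    tx_rows <- ref_gm[ref_gm$gene_id == dg$gene, ]
    tx_rows <- tx_rows[tx_rows$transcript_id == tx_rows$transcript_id[1], ]
    full <- nrow(tx_rows) > 0 &&
      ev$start <= min(tx_rows$exon_start) && ev$end >= max(tx_rows$exon_end)
    if (moi == "AD" && full &&
        ((ev$resolved_type == "DEL" && isTRUE(dg$haploinsufficient)) ||
         (ev$resolved_type == "DUP" && isTRUE(dg$triplosensitive)))) {
      items <- dplyr::bind_rows(items, evidence_item(
        "2-established-region", scheme$established_region,
        rationale = paste0("complete overlap of established dosage-sensitive gene ",
                           dg$gene)))
    } else if (ev$resolved_type %in% c("DEL", "INS", "INV") &&
               nrow(tx_rows) > 0) {
      s <- pvs1_strength(ev$chrom, ev$start, ev$end, ev$resolved_type,
                         tx_rows, established = TRUE)
      if (s != "none") {
        items <- dplyr::bind_rows(items, evidence_item(
          "2E-PVS1", strength_to_points(s, scheme), strength_label = s,
          rationale = paste0("LoF in established gene ", dg$gene)))
      }
    }
  }
  if (ev$resolved_type %in% c("DEL", "DUP")) {
    items <- dplyr::bind_rows(items,
                              score_gene_number(ev$resolved_type, ev$n_genes,
                                                scheme))
  }
  if (!is.null(obs)) {
    if (identical(moi, "AR")) {
      items <- dplyr::bind_rows(items, score_ar_cases(obs, scheme))
    } else if (identical(moi, "XL")) {
      items <- dplyr::bind_rows(items, score_xl_cases(obs, scheme))
    } else {
      dn <- obs$de_novo[!is.na(obs$de_novo)]
      if (length(dn) > 0) {
        best <- names(scheme$de_novo)[min(match(dn, names(scheme$de_novo)))]
        items <- dplyr::bind_rows(items, score_de_novo(best, scheme))
      }
      items <- dplyr::bind_rows(items, score_phenotype(obs, scheme))
    }
    fn <- obs$functional_evidence[!is.na(obs$functional_evidence)]
    if (length(fn) > 0) {
      lev <- names(scheme$functional)
      best_fn <- lev[max(match(fn, lev))]
      items <- dplyr::bind_rows(items, score_functional(best_fn, scheme))
    }
  }
  aggregate_evidence(items, scheme, event_id = ev$event_id)
}

#' Size bins used in cohort summaries
#' @keywords internal
size_bin <- function(len) {
  cut(len, breaks = c(0, 1e3, 1e4, 1e5, 1e6, 1e7, Inf),
      labels = c("<1kb", "1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb",
                 ">10Mb"), right = FALSE)
}

#' Gene-count bins matching the section-3 scoring cutoffs
#' @keywords internal
gene_bin <- function(n) {
  cut(n, breaks = c(-Inf, 24, 34, 49, Inf),
      labels = c("0-24", "25-34", "35-49", "50+"))
}

#' Cohort-level summary tables for classified events
#'
#' Counts events by estimated size bin (powers-of-ten edges from 1 kb to
#' 10 Mb with open tails), resolved type, classification, gene-count bin
#' (section-3 cutoffs) and, when available, mode of inheritance. Marginals
#' of each table equal the total event count.
#'
#' @param events Classified event tibble from [classify_events()].
#' @return Named list of tibbles: `by_size`, `by_type`, `by_class`,
#'   `by_genes`, `type_by_class`, `size_by_class`.
#' @export
summarize_events <- function(events) {
  ev <- dplyr::mutate(events,
                      size_bin = size_bin(.data$end - .data$start),
                      gene_bin = if ("n_genes" %in% names(events))
                        gene_bin(.data$n_genes) else NA)
  cls <- if ("classification" %in% names(ev)) "classification" else NULL
  list(
    by_size = dplyr::count(ev, .data$size_bin, .drop = FALSE),
    by_type = dplyr::count(ev, .data$resolved_type),
    by_class = if (!is.null(cls)) dplyr::count(ev, .data$classification)
               else tibble::tibble(),
    by_genes = dplyr::count(ev, .data$gene_bin, .drop = FALSE),
    type_by_class = if (!is.null(cls))
      dplyr::count(ev, .data$resolved_type, .data$classification)
      else tibble::tibble(),
    size_by_class = if (!is.null(cls))
      dplyr::count(ev, .data$size_bin, .data$classification, .drop = FALSE)
      else tibble::tibble()
  )
}

#' Plot event counts by size bin and classification
#' @param events Classified event tibble.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(events) {
  d <- dplyr::mutate(events, size_bin = size_bin(.data$end - .data$start))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$size_bin))
  if ("classification" %in% names(d)) {
    p <- p + ggplot2::geom_bar(ggplot2::aes(fill = .data$classification))
  } else {
    p <- p + ggplot2::geom_bar(fill = "steelblue")
  }
  p + ggplot2::labs(x = "estimated size", y = "events") +
    ggplot2::theme_minimal()
}

#' Plot event counts by resolved type
#' @param events Classified event tibble.
#' @return A ggplot object.
#' @export
plot_type_distribution <- function(events) {
  ggplot2::ggplot(events, ggplot2::aes(x = .data$resolved_type)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "resolved type", y = "events") +
    ggplot2::theme_minimal()
}

#' Run the full post-processing and classification pipeline
#'
#' Stages: read or accept calls; per-sample QC; same-allele clustering and
#' frequencies; exon-count annotation; high-confidence flagging;
#' mode-of-inheritance frequency screen (recessive limit by default, the
#' permissive cohort-level screen); fragment merging; complex-candidate
#' flagging; optional validation resolution; gene-content, population-panel
#' and microarray annotation; classification; summary. Each stage's output
#' is returned (and optionally written under `out_dir`); reruns on the same
#' inputs are deterministic.
#'
#' @param calls Call tibble (or path read with [read_segments()] when a
#'   character scalar plus `dialect` is given).
#' @param gene_models Exon-level gene model tibble (one or more sources).
#' @param dosage Dosage table (optional).
#' @param probes Probe tibble (optional; microarray stage skipped if NULL).
#' @param panel Population panel tibble (optional).
#' @param observations Case observations (optional).
#' @param ped Pedigree tibble (optional, used for allele counting on chrX).
#' @param validation Validation records (optional).
#' @param moi Frequency screen to apply: `"recessive"` (default) or
#'   `"dominant"`.
#' @param scheme A [scoring_scheme()].
#' @param thresholds A [qs_thresholds()]; pass `apply_qs = FALSE` to disable
#'   the QS screen (low-quality rescue analyses).
#' @param apply_qs Apply the QS component of the high-confidence screen.
#' @param limits A [moi_limits()].
#' @param max_gap_bp,window_bp Merge gap and complex-candidate window.
#' @param dialect Dialect when `calls` is a path.
#' @param out_dir Optional output directory for TSV/BED/JSON artifacts.
#' @return List with `calls`, `qc`, `filtered`, `events`, `classified`,
#'   `summary`.
#' @export
run_pipeline <- function(calls, gene_models, dosage = NULL, probes = NULL,
                         panel = NULL, observations = NULL, ped = NULL,
                         validation = NULL,
                         moi = c("recessive", "dominant"),
                         scheme = scoring_scheme(),
                         thresholds = qs_thresholds(), apply_qs = TRUE,
                         limits = moi_limits(), max_gap_bp = 1e6,
                         window_bp = 2e6, dialect = "sv_vcf",
                         out_dir = NULL) {
  moi <- match.arg(moi)
  if (is.character(calls)) calls <- read_segments(calls, dialect, ped = ped)
  qc <- sample_qc(calls)
  clustered <- cluster_alleles(calls, ped = ped)
  clustered <- annotate_exon_counts(clustered, gene_models)
  flagged <- flag_high_confidence(clustered, qc, thresholds)
  if (!apply_qs) {
    flagged$high_confidence <- flagged$frequency <= 0.01 &
      flagged$n_exons >= 3 & qc$is_high_quality[
        match(flagged$sample_id, qc$sample_id)]
  }
  filtered <- filter_by_moi(dplyr::filter(flagged, .data$high_confidence),
                            moi, limits)
  events <- merge_fragments(filtered, max_gap_bp = max_gap_bp)
  events <- flag_complex_candidate(events, window_bp = window_bp)
  if (!is.null(validation)) events <- resolve_with_validation(events, validation)
  events <- annotate_gene_content(events, gene_models, dosage)
  if (!is.null(panel)) events <- match_population_sv(events, panel)
  if (!is.null(probes)) events <- cma_detectable(events, probes)
  classified <- classify_events(events, gene_models, dosage, observations,
                                scheme)
  summary <- summarize_events(classified)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_bed(classified, file.path(out_dir, "events.bed"))
    readr::write_tsv(
      dplyr::select(classified, -dplyr::any_of(c(
        "components", "result", "gene_counts", "genes", "exon_counts",
        "disease_genes"))),
      file.path(out_dir, "classified.tsv"))
    evid <- purrr::map_dfr(seq_len(nrow(classified)), function(i) {
      dplyr::mutate(tidy(classified$result[[i]]),
                    event_id = classified$event_id[i], .before = 1)
    })
    readr::write_tsv(evid, file.path(out_dir, "evidence_lines.tsv"))
    jsonlite::write_json(
      list(n_calls = nrow(calls), n_filtered = nrow(filtered),
           n_events = nrow(events),
           classifications = as.list(table(classified$classification))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE)
  }
  list(calls = calls, qc = qc, filtered = filtered, events = events,
       classified = classified, summary = summary)
}
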