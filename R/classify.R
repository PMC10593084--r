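#' Scoring scheme for the quantitative pathogenicity engine
#'
#' All point values, caps, bins and classification ranges used by the engine
#' live in one editable configuration object. Defaults:
#'
#' * Strength ladder: very strong (PVS1) 0.90, strong 0.45, moderate 0.30,
#'   supporting 0.15.
#' * Gene-number bins (section-3 style): deletions score 0 for 0-24 genes,
#'   0.45 for 25-34 and 0.90 from 35 up; copy gains score 0 for 0-34, 0.45
#'   for 35-49 and 0.90 from 50 up. The printed bins leave the exact upper
#'   boundary counts unassigned; they are placed in the 0.90 bin to keep the
#'   bins contiguous (configurable).
#' * Autosomal-recessive case table (PM3-style, per proband): confirmed in
#'   trans with P or LP second variant 0.30; phase unknown 0.15 (P) / 0.08
#'   (LP); homozygous 0.15 with aggregate cap 0.30; VUS in trans 0.08 with
#'   aggregate cap 0.16 (phase-unknown VUS 0). Aggregate case evidence cap
#'   0.90.
#' * Phenotype specificity: 0.15 for a unique phenotype, 0.30 when evidence
#'   is particularly strong; applied once per variant.
#' * Functional evidence: supporting 0.15, moderate 0.30, strong 0.45.
#' * De novo occurrence: confirmed 0.45, assumed 0.30.
#' * X-linked case table: explicit per-branch values (documented package
#'   defaults, not anchored to published numbers) keyed by proband sex and
#'   inheritance; phenotype adjustment bounded so one case contributes at
#'   most `xl_case_max` = 0.45.
#' * Classification ranges: total >= 0.99 pathogenic (P); 0.90-0.98 likely
#'   pathogenic (LP); -0.89-0.89 uncertain (VUS); -0.98 to -0.90 likely
#'   benign (LB); <= -0.99 benign (B).
#'
#' @param ... Named overrides of any top-level element.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(...) {
  scheme <- list(
    strength_points = c(PVS1 = 0.90, strong = 0.45, moderate = 0.30,
                        supporting = 0.15, none = 0),
    gene_bins = list(DEL = c(mid = 25, high = 35),
                     DUP = c(mid = 35, high = 50)),
    gene_bin_points = c(0, 0.45, 0.90),
    ar = list(in_trans_P = 0.30, in_trans_LP = 0.30,
              phase_unknown_P = 0.15, phase_unknown_LP = 0.08,
              hom = 0.15, hom_cap = 0.30,
              vus_in_trans = 0.08, vus_cap = 0.16,
              case_cap = 0.90),
    phenotype = c(none = 0, unique = 0.15, unique_strong = 0.30),
    functional = c(none = 0, supporting = 0.15, moderate = 0.30,
                   strong = 0.45),
    de_novo = c(confirmed = 0.45, assumed = 0.30, inherited_affected = 0,
                inherited_unaffected = 0, unknown = 0),
    xl_table = c(
      "M.confirmed" = 0.30, "M.assumed" = 0.15,
      "M.inherited_affected" = 0.30, "M.inherited_unaffected" = 0.15,
      "M.unknown" = 0.08,
      "F.confirmed" = 0.30, "F.assumed" = 0.15,
      "F.inherited_affected" = 0.15, "F.inherited_unaffected" = 0.08,
      "F.unknown" = 0
    ),
    xl_case_max = 0.45,
    established_region = 1.0,
    ranges = c(P = 0.99, LP = 0.90, LB = -0.90, B = -0.99)
  )
  dots <- list(...)
  for (nm in names(dots)) scheme[[nm]] <- dots[[nm]]
  stopifnot(scheme$ranges["P"] > scheme$ranges["LP"],
            scheme$ranges["LP"] > scheme$ranges["LB"],
            scheme$ranges["LB"] > scheme$ranges["B"])
  structure(scheme, class = "scoring_scheme")
}

#' Map an evidence strength tier onto engine points
#' @param strength One of `"PVS1"`, `"strong"`, `"moderate"`, `"supporting"`,
#'   `"none"` (vectorized).
#' @param scheme A [scoring_scheme()].
#' @return Numeric points.
#' @export
strength_to_points <- function(strength, scheme = scoring_scheme()) {
  if (!all(strength %in% names(scheme$strength_points))) {
    rlang::abort("unknown strength tier")
  }
  unname(scheme$strength_points[strength])
}

#' @keywords internal
evidence_item <- function(category, points, strength_label = NA_character_,
                          rationale = NA_character_, cap_applied = FALSE) {
  tibble::tibble(category = category, points = points,
                 strength_label = strength_label, rationale = rationale,
                 cap_applied = cap_applied)
}

#' @keywords internal
empty_evidence <- function() evidence_item(character(), numeric(),
                                           character(), character(),
                                           logical())[0, ]

#' Loss-of-function (PVS1-style) strength for an event in an established gene
#'
#' Decision tree for the very-strong loss-of-function criterion (category 2E
#' for dosage curation). Eligibility: deletions always; insertions when they
#' land within an exon; inversions when exactly one breakpoint falls within
#' the gene, or both breakpoints fall within the gene and the inversion
#' spans at least one exon; duplications only when explicitly flagged as
#' disrupting the reading frame intragenically.
#'
#' Strength for eligible events: removal of the whole transcript, or a
#' frameshifting change predicted to trigger nonsense-mediated decay (the
#' premature termination point lies more than 50 nt upstream of the last
#' exon-exon junction in coding coordinates), scores the full PVS1 tier;
#' changes escaping NMD but removing more than 10% of the coding sequence
#' score strong; smaller removals score moderate (a whole exon) or
#' supporting (partial exon).
#'
#' @param chrom,start,end Event span (0-based half-open).
#' @param svtype Event type: `"DEL"`, `"DUP"`, `"INS"`, `"INV"`.
#' @param transcript One transcript's exon rows from a gene model tibble
#'   (must carry `cds_start`/`cds_end` for coding logic).
#' @param established Is the gene-disease relationship established? The LoF
#'   path requires it; unestablished genes go through case evidence instead.
#' @param dup_disruptive Treat an intragenic duplication as frame-disrupting.
#' @param nmd_rule_nt The NMD boundary distance (50 nt).
#' @return One of `"PVS1"`, `"strong"`, `"moderate"`, `"supporting"`,
#'   `"none"`.
#' @export
pvs1_strength <- function(chrom, start, end, svtype, transcript,
                          established = TRUE, dup_disruptive = FALSE,
                          nmd_rule_nt = 50) {
  if (!established) {
    rlang::abort("gene-disease relationship not established: use case-evidence path")
  }
  tx <- dplyr::arrange(transcript, .data$exon_start)
  if (norm_chrom(tx$chrom[1]) != norm_chrom(chrom)) return("none")
  gene_start <- min(tx$exon_start)
  gene_end <- max(tx$exon_end)
  ov <- exons_overlapped(chrom, start, end, tx)
  eligible <- switch(svtype,
    DEL = TRUE,
    INS = ov$count >= 1,
    INV = {
      bp_in <- c(start >= gene_start & start < gene_end,
                 end > gene_start & end <= gene_end)
      sum(bp_in) == 1 || (all(bp_in) && ov$count >= 1)
    },
    DUP = dup_disruptive,
    FALSE)
  if (!eligible) return("none")
  # full-gene removal
  if (svtype == "DEL" && start <= gene_start && end >= gene_end) return("PVS1")
  cds_start <- tx$cds_start[1]
  cds_end <- tx$cds_end[1]
  if (is.na(cds_start)) return("none")   # non-coding transcript: no LoF call
  cds_len_per_exon <- pmax(0, pmin(tx$exon_end, cds_end) -
                                pmax(tx$exon_start, cds_start))
  total_cds <- sum(cds_len_per_exon)
  if (total_cds == 0) return("none")
  # coding offset of a genomic position, strand-aware
  coding_offset <- function(pos) {
    if (tx$strand[1] == "-") {
      sum(pmax(0, pmin(tx$exon_end, cds_end) - pmax(tx$exon_start, cds_start, pos)))
    } else {
      sum(pmax(0, pmin(tx$exon_end, cds_end, pos) - pmax(tx$exon_start, cds_start)))
    }
  }
  coding_exons <- which(cds_len_per_exon > 0)
  last_cds_exon_len <- cds_len_per_exon[
    if (tx$strand[1] == "-") coding_exons[1] else coding_exons[length(coding_exons)]]
  nmd_boundary <- total_cds - last_cds_exon_len - nmd_rule_nt
  if (svtype %in% c("INS", "INV")) {
    # disruption junction: the first breakpoint inside the gene
    bp <- if (start >= gene_start && start < gene_end) start else end
    off <- coding_offset(if (tx$strand[1] == "-") bp else bp)
    return(if (off <= nmd_boundary) "PVS1" else "strong")
  }
  removed_cds <- sum(pmax(0, pmin(tx$exon_end, cds_end, end) -
                               pmax(tx$exon_start, cds_start, start)))
  if (removed_cds == 0) return("none")
  frameshift <- removed_cds %% 3 != 0
  involves_last_exon <- if (tx$strand[1] == "-") {
    start < tx$exon_end[coding_exons[1]] && end > tx$exon_start[coding_exons[1]]
  } else {
    k <- coding_exons[length(coding_exons)]
    start < tx$exon_end[k] && end > tx$exon_start[k]
  }
  stop_offset <- coding_offset(if (tx$strand[1] == "-") end else start)
  if (frameshift && !involves_last_exon && stop_offset <= nmd_boundary) {
    return("PVS1")
  }
  frac <- removed_cds / total_cds
  if (frac > 0.10) return("strong")
  whole_exon <- any(tx$exon_start >= start & tx$exon_end <= end)
  if (whole_exon) "moderate" else "supporting"
}

#' Gene-number (section 3) evidence
#'
#' Deletions: 0 points below `mid` genes, 0.45 from `mid` to `high - 1`,
#' 0.90 from `high`; defaults mid 25 / high 35. Copy gains: defaults mid 35 /
#' high 50.
#' @param svtype `"DEL"` or `"DUP"`.
#' @param n_genes Protein-coding gene count (non-negative).
#' @param scheme A [scoring_scheme()].
#' @return One evidence-item row.
#' @export
score_gene_number <- function(svtype, n_genes, scheme = scoring_scheme()) {
  if (n_genes < 0) rlang::abort("negative gene count")
  bins <- scheme$gene_bins[[match.arg(svtype, c("DEL", "DUP"))]]
  pts <- scheme$gene_bin_points[
    1 + (n_genes >= bins[["mid"]]) + (n_genes >= bins[["high"]])]
  evidence_item("3-gene-count", pts,
                rationale = sprintf("%s spanning %d protein-coding genes",
                                    svtype, as.integer(n_genes)))
}

#' Autosomal-recessive case evidence (PM3-style table)
#'
#' Scores per-proband observations of the variant in an established
#' autosomal-recessive gene. Per proband: confirmed in trans with a P/LP
#' second variant 0.30; phase unknown 0.15 (P) / 0.08 (LP); homozygous 0.15
#' (aggregate cap 0.30); VUS in trans 0.08 (aggregate cap 0.16; phase-unknown
#' VUS scores 0); observations in cis score 0. Aggregate case evidence is
#' capped (default 0.90). A once-per-variant phenotype-specificity bonus
#' (0.15, or 0.30 when particularly strong) is emitted as a separate item.
#'
#' @param observations Observation tibble (see [read_observations()]): needs
#'   `zygosity`, `phase`, `second_variant_class`, `phenotype_specificity`.
#' @param scheme A [scoring_scheme()].
#' @return Evidence-item tibble (case row, plus a phenotype row when earned).
#' @export
score_ar_cases <- function(observations, scheme = scoring_scheme()) {
  ar <- scheme$ar
  per <- purrr::pmap_dbl(observations[, c("zygosity", "phase",
                                          "second_variant_class")],
    function(zygosity, phase, second_variant_class) {
      if (phase == "in_cis") return(0)
      if (zygosity == "hom") return(ar$hom)
      if (second_variant_class %in% c("P", "LP")) {
        if (phase == "in_trans_confirmed") {
          if (second_variant_class == "P") ar$in_trans_P else ar$in_trans_LP
        } else {
          if (second_variant_class == "P") ar$phase_unknown_P
          else ar$phase_unknown_LP
        }
      } else if (second_variant_class == "VUS") {
        if (phase == "in_trans_confirmed") ar$vus_in_trans else 0
      } else 0
    })
  is_hom <- observations$zygosity == "hom" & observations$phase != "in_cis"
  is_vus <- !is_hom & observations$second_variant_class == "VUS" &
    observations$phase == "in_trans_confirmed"
  hom_pts <- min(sum(per[is_hom]), ar$hom_cap)
  vus_pts <- min(sum(per[is_vus]), ar$vus_cap)
  other_pts <- sum(per[!is_hom & !is_vus])
  raw <- hom_pts + vus_pts + other_pts
  total <- min(raw, ar$case_cap)
  items <- evidence_item(
    "4-AR-case", total,
    rationale = sprintf("%d proband observation(s)", nrow(observations)),
    cap_applied = total < raw || sum(per[is_hom]) > ar$hom_cap ||
      sum(per[is_vus]) > ar$vus_cap)
  dplyr::bind_rows(items, score_phenotype(observations, scheme))
}

#' Phenotype-specificity bonus (applied once per variant)
#'
#' 0.15 points when at least one reported individual has a phenotype highly
#' specific to the disease (low genetic heterogeneity); 0.30 when the
#' evidence is particularly strong (specific unique phenotype with
#' high-sensitivity clinical testing and consistent family history).
#' @param observations Observation tibble with `phenotype_specificity`
#'   (`"none"`, `"unique"`, `"unique_strong"`).
#' @param scheme A [scoring_scheme()].
#' @return Evidence-item tibble (zero rows when no bonus is earned).
#' @export
score_phenotype <- function(observations, scheme = scoring_scheme()) {
  lv <- observations$phenotype_specificity
  if (!all(lv %in% names(scheme$phenotype))) {
    rlang::abort("unknown phenotype_specificity level")
  }
  best <- max(scheme$phenotype[lv], 0)
  if (best == 0) return(empty_evidence())
  evidence_item("PP4-like", best,
                rationale = "unique phenotype reported; applied once per variant")
}

#' X-linked case evidence
#'
#' Scores per-proband observations in an established X-linked gene from a
#' fully explicit point table keyed by proband sex and de novo / inheritance
#' status (with carrier-parent affected status folded into the inheritance
#' key). The table values are package configuration defaults, editable via
#' [scoring_scheme()]. A phenotype-specificity adjustment is added per case
#' and the per-case contribution is bounded at `xl_case_max` (0.45).
#' Observations in cis score 0.
#'
#' @param observations Observation tibble: needs `sex`, `de_novo`,
#'   `phenotype_specificity`, optionally `phase`.
#' @param scheme A [scoring_scheme()].
#' @return One evidence-item row.
#' @export
score_xl_cases <- function(observations, scheme = scoring_scheme()) {
  if (any(is.na(observations$sex))) rlang::abort("proband sex is required for X-linked scoring")
  per <- purrr::pmap_dbl(
    list(observations$sex, observations$de_novo,
         observations$phenotype_specificity,
         if ("phase" %in% names(observations)) observations$phase
         else rep("unknown", nrow(observations))),
    function(sex, de_novo, pheno, phase) {
      if (identical(phase, "in_cis")) return(0)
      key <- paste(sex, de_novo, sep = ".")
      base <- scheme$xl_table[key]
      if (is.na(base)) base <- 0
      min(base + scheme$phenotype[pheno], scheme$xl_case_max)
    })
  evidence_item("4-XL-case", sum(per),
                rationale = sprintf("%d proband observation(s), per-case cap %.2f",
                                    nrow(observations), scheme$xl_case_max))
}

#' De novo occurrence evidence
#' @param de_novo One of `"confirmed"`, `"assumed"`, `"inherited_affected"`,
#'   `"inherited_unaffected"`, `"unknown"`.
#' @param scheme A [scoring_scheme()].
#' @return One evidence-item row (zero rows when nothing is earned).
#' @export
score_de_novo <- function(de_novo, scheme = scoring_scheme()) {
  if (!de_novo %in% names(scheme$de_novo)) rlang::abort("unknown de novo status")
  pts <- scheme$de_novo[[de_novo]]
  if (pts == 0) return(empty_evidence())
  evidence_item("5-de-novo", pts, rationale = paste0("de novo ", de_novo))
}

#' Functional evidence
#'
#' Supporting functional evidence of pathogenicity (expression assays, RNA
#' sequencing, cellular or protein-interaction studies) adds 0.15 points;
#' stronger results upgrade to moderate (0.30) or strong (0.45; e.g. an
#' animal model with the exact variant recapitulating the phenotype).
#' @param level `"none"`, `"supporting"`, `"moderate"` or `"strong"`.
#' @param scheme A [scoring_scheme()].
#' @return One evidence-item row (zero rows for `"none"`).
#' @export
score_functional <- function(level, scheme = scoring_scheme()) {
  if (!level %in% names(scheme$functional)) rlang::abort("unknown functional level")
  pts <- scheme$functional[[level]]
  if (pts == 0) return(empty_evidence())
  evidence_item("FUNC", pts, strength_label = level,
                rationale = paste0(level, " functional evidence"))
}

#' Aggregate evidence items into a five-tier classification
#'
#' The total is the sum of (already capped) evidence points; the tier is read
#' off the configured ranges: pathogenic at and above 0.99, likely pathogenic
#' from 0.90, benign at and below -0.99, likely benign from -0.90, uncertain
#' significance between.
#'
#' @param items Evidence-item tibble.
#' @param scheme A [scoring_scheme()].
#' @param event_id Optional event reference carried on the result.
#' @return A `cnv_classification` object (see [tidy.cnv_classification()]).
#' @export
aggregate_evidence <- function(items, scheme = scoring_scheme(),
                               event_id = NA_character_) {
  if (nrow(items) > 0 && any(!is.finite(items$points))) {
    rlang::abort("non-finite evidence points")
  }
  total <- if (nrow(items)) sum(items$points) else 0
  r <- scheme$ranges
  classification <- if (total >= r[["P"]]) "P"
    else if (total >= r[["LP"]]) "LP"
    else if (total <= r[["B"]]) "B"
    else if (total <= r[["LB"]]) "LB"
    else "VUS"
  structure(list(event_id = event_id, items = items, total = total,
                 classification = classification, component_results = NULL),
            class = "cnv_classification")
}

#' @export
print.cnv_classification <- function(x, ...) {
  cat(sprintf("<cnv_classification> %s  total = %.2f  ->  %s\n",
              ifelse(is.na(x$event_id), "", x$event_id), x$total,
              x$classification))
  if (nrow(x$items)) print(x$items[, c("category", "points", "rationale")])
  invisible(x)
}

#' Five-tier ordering used for complex events
#' @keywords internal
tier_levels <- c("B", "LB", "VUS", "LP", "P")

#' Classification of a complex event from its component classifications
#'
#' Each canonical component of a complex rearrangement is classified
#' separately and the event defaults to the most deleterious component
#' classification under the ordering B < LB < VUS < LP < P.
#'
#' @param component_results List of `cnv_classification` objects.
#' @param event_id Optional event reference.
#' @return A `cnv_classification` whose classification is the most
#'   deleterious component tier; components are retained.
#' @export
classify_complex <- function(component_results, event_id = NA_character_) {
  if (length(component_results) == 0) rlang::abort("no component results")
  tiers <- vapply(component_results, function(r) r$classification, character(1))
  worst <- tier_levels[max(match(tiers, tier_levels))]
  best_idx <- which.max(match(tiers, tier_levels))
  out <- structure(list(
    event_id = event_id,
    items = component_results[[best_idx]]$items,
    total = component_results[[best_idx]]$total,
    classification = worst,
    component_results = component_results), class = "cnv_classification")
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the evidence lines of a classification
#' @param x A `cnv_classification`.
#' @param ... Unused.
#' @return Tibble of evidence items.
#' @method tidy cnv_classification
#' @export
tidy.cnv_classification <- function(x, ...) x$items

#' One-row summary of a classification
#' @param x A `cnv_classification`.
#' @param ... Unused.
#' @return One-row tibble: `event_id`, `n_items`, `total`, `classification`.
#' @method glance cnv_classification
#' @export
glance.cnv_classification <- function(x, ...) {
  tibble::tibble(event_id = x$event_id, n_items = nrow(x$items),
                 total = x$total, classification = x$classification)
}

#' Evidence-line bar chart for a classification
#' @param object A `cnv_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_classification
#' @export
autoplot.cnv_classification <- function(object, ...) {
  d <- object$items
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$category,
                                                     .data$points),
                                  y = .data$points)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "points",
                  title = sprintf("total %.2f -> %s", object$total,
                                  object$classification)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
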