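#' Configuration for the synthetic reference and cohort generator
#'
#' The generator emulates the structure of an exome read-depth CNV callset
#' from a rare-disease cohort: a gene model with two annotation sources that
#' disagree on gene content, an array probe set, a population SV panel,
#' per-sample raw calls dominated by low-quality artifacts (so that samples
#' carry tens of autosomal calls with QS just above 20, as real samples do),
#' a small number of rare high-quality incidental calls per sample, common
#' benign CNVs segregating at panel frequency, and implanted causal events —
#' an autosomal-dominant de novo multi-gene deletion, an autosomal-recessive
#' intragenic deletion in trans with a pathogenic SNV, and an X-linked
#' hemizygous deletion — optionally emitted as several fragments the way
#' large events are fragmented by read-depth callers.
#'
#' @param seed Integer seed; the same seed reproduces every output exactly.
#' @param n_samples Cohort size (default 100).
#' @param n_genes Autosomal genes (default 150, on chr1).
#' @param n_x_genes Genes on chrX (default 6).
#' @param exons_per_gene Range of exon counts per gene.
#' @param exon_len_range Range of exon lengths (bp).
#' @param intron_len Intron length (bp).
#' @param gene_gap Intergenic gap (bp).
#' @param probe_density Array probes per kb (default 0.1).
#' @param panel_size Population panel entries (default 100).
#' @param benign_carrier_freq Carrier frequency of the implanted common
#'   benign deletion (default 0.05).
#' @param rare_benign_rate Mean rare incidental high-quality calls per sample
#'   (default 2).
#' @param n_noise_calls Low-quality artifact calls per sample (default 45).
#' @param fragmentation_prob Probability the large dominant implant is
#'   emitted fragmented (default 1 fragment block, see `frag_range`).
#' @param frag_range Range of fragment counts when fragmenting.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_samples = 100, n_genes = 150,
                         n_x_genes = 6, exons_per_gene = c(5, 10),
                         exon_len_range = c(130, 170), intron_len = 2000,
                         gene_gap = 150000, probe_density = 0.1,
                         panel_size = 100, benign_carrier_freq = 0.05,
                         rare_benign_rate = 2, n_noise_calls = 45,
                         fragmentation_prob = 0.5, frag_range = c(2, 4)) {
  stopifnot(benign_carrier_freq >= 0, benign_carrier_freq <= 1,
            fragmentation_prob >= 0, fragmentation_prob <= 1,
            probe_density > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' @keywords internal
lay_genes <- function(chrom, n, cfg, offset = 1e5, prefix = "G") {
  rows <- list()
  pos <- offset
  for (i in seq_len(n)) {
    k <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
    lens <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]), k,
                   replace = TRUE)
    starts <- pos + c(0, cumsum(lens[-k] + cfg$intron_len))
    ends <- starts + lens
    gid <- sprintf("%s%03d", prefix, i)
    rows[[i]] <- tibble::tibble(
      gene_id = gid, gene_name = gid, transcript_id = paste0(gid, ".t1"),
      biotype = if (i %% 6 == 0) "other" else "protein_coding",
      strand = if (i %% 5 == 0) "-" else "+",
      chrom = chrom, exon_start = starts, exon_end = ends,
      cds_start = starts[1] + 20, cds_end = ends[k] - 20)
    pos <- ends[k] + cfg$gene_gap
  }
  list(genes = dplyr::bind_rows(rows), chrom_len = pos)
}

#' Generate a synthetic reference: gene models, probes, panel, dosage table
#'
#' Genes are non-overlapping with realistic exon/intron structure on chr1
#' and chrX. Two annotation sources are emitted: a complete "ensembl-like"
#' source and a curated "omim-like" source missing a deterministic subset of
#' genes, so that multi-gene events show source-discordant gene counts.
#' Probes are Poisson-placed at the configured density; the panel mixes
#' common and rare SVs and contains the locus of the implanted common benign
#' deletion at its true frequency.
#'
#' @param cfg A [synth_config()].
#' @return List: `gene_models` (both sources), `probes`, `panel`, `dosage`,
#'   `implant_genes` (designated disease genes), `chrom_len`.
#' @export
generate_reference <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  aut <- lay_genes("chr1", cfg$n_genes, cfg, prefix = "G")
  xg <- lay_genes("chrX", cfg$n_x_genes, cfg, prefix = "XG")
  ensembl <- dplyr::bind_rows(aut$genes, xg$genes) |>
    dplyr::mutate(source_label = "ensembl-like")
  # designated disease genes (forced protein coding, kept in both sources)
  pc <- unique(ensembl$gene_id[ensembl$biotype == "protein_coding" &
                                 ensembl$chrom == "chr1"])
  ad_gene <- pc[10]
  ar_gene <- pc[20]
  benign_gene <- pc[30]
  xl_gene <- ensembl$gene_id[ensembl$chrom == "chrX" &
                               ensembl$biotype == "protein_coding"][1]
  keep <- unique(ensembl$gene_id)
  drop <- keep[seq_along(keep) %% 7 == 0]
  drop <- setdiff(drop, c(ad_gene, ar_gene, xl_gene, benign_gene))
  omim <- ensembl |>
    dplyr::filter(!.data$gene_id %in% drop) |>
    dplyr::mutate(source_label = "omim-like")
  gene_models <- gene_model_cols(dplyr::bind_rows(omim, ensembl))
  chrom_len <- c(chr1 = aut$chrom_len, chrX = xg$chrom_len)
  probes <- purrr::map_dfr(names(chrom_len), function(ch) {
    n <- stats::rpois(1, chrom_len[[ch]] / 1000 * cfg$probe_density)
    s <- sort(sample.int(chrom_len[[ch]] - 60, n))
    tibble::tibble(chrom = ch, start = s, end = s + 60)
  }) |> dplyr::mutate(platform_label = "synthetic-array")
  # benign implant locus: the full span of benign_gene plus margins
  bg <- ensembl[ensembl$gene_id == benign_gene, ]
  benign_locus <- tibble::tibble(chrom = "chr1",
                                 start = min(bg$exon_start) - 500,
                                 end = max(bg$exon_end) + 500,
                                 svtype = "DEL",
                                 af = cfg$benign_carrier_freq / 2)
  rest <- tibble::tibble(
    chrom = "chr1",
    start = sort(sample.int(chrom_len[["chr1"]] - 20000,
                            cfg$panel_size - 1)),
    len = sample(500:20000, cfg$panel_size - 1, replace = TRUE),
    svtype = sample(c("DEL", "DUP"), cfg$panel_size - 1, replace = TRUE),
    common = stats::runif(cfg$panel_size - 1) < 0.3
  ) |>
    dplyr::mutate(end = .data$start + .data$len,
                  af = ifelse(.data$common, stats::runif(dplyr::n(), 0.01, 0.2),
                              stats::runif(dplyr::n(), 1e-4, 0.009))) |>
    dplyr::select("chrom", "start", "end", "svtype", "af")
  panel <- dplyr::arrange(dplyr::bind_rows(benign_locus, rest),
                          .data$chrom, .data$start) |>
    dplyr::mutate(panel_label = "synthetic-panel")
  dosage <- tibble::tibble(
    gene = c(ad_gene, ar_gene, xl_gene, pc[5], pc[25]),
    moi = c("AD", "AR", "XL", "AD", "AR"),
    established = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    haploinsufficient = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    triplosensitive = FALSE)
  list(gene_models = gene_models, probes = probes, panel = panel,
       dosage = dosage,
       implant_genes = list(ad = ad_gene, ar = ar_gene, xl = xl_gene,
                            benign = benign_gene),
       chrom_len = chrom_len)
}

#' @keywords internal
gene_span <- function(gm, gene) {
  g <- gm[gm$gene_id == gene & gm$source_label == "ensembl-like", ]
  c(chrom = g$chrom[1], start = min(g$exon_start), end = max(g$exon_end))
}

#' @keywords internal
pick_ar_window <- function(tx) {
  # choose a run of internal exons whose removed CDS length is frameshifting
  tx <- dplyr::arrange(tx, .data$exon_start)
  k <- nrow(tx)
  cds_len <- pmax(0, pmin(tx$exon_end, tx$cds_end[1]) -
                       pmax(tx$exon_start, tx$cds_start[1]))
  for (w in 3:max(3, k - 2)) for (j in 2:(k - w)) {
    if (j + w - 1 >= k) next
    if (sum(cds_len[j:(j + w - 1)]) %% 3 != 0) {
      return(c(start = tx$exon_start[j] - 200,
               end = tx$exon_end[j + w - 1] + 200))
    }
  }
  c(start = tx$exon_start[2] - 200, end = tx$exon_end[min(4, k - 1)] + 151)
}

#' Generate a synthetic cohort with known truth
#'
#' Implants (one sample each unless stated): an autosomal-dominant de novo
#' multi-gene deletion spanning the established haploinsufficient gene and
#' its neighbours, possibly fragmented into 2-6 calls cut at intergenic
#' boundaries; an autosomal-recessive intragenic frameshifting multi-exon
#' deletion reported in trans with a pathogenic SNV; an X-linked hemizygous
#' whole-gene deletion in a male proband; and a common benign deletion
#' carried by `benign_carrier_freq` of samples at the panel locus. Adds
#' per-sample low-QS artifact calls and rare incidental high-quality calls
#' away from the implant loci.
#'
#' @param reference Output of [generate_reference()].
#' @param cfg The same [synth_config()].
#' @return List: `calls`, `ped`, `observations`, `truth`.
#' @export
generate_cohort <- function(reference, cfg = synth_config()) {
  set.seed(cfg$seed + 1)
  gm <- reference$gene_models
  ens <- gm[gm$source_label == "ensembl-like", ]
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  sex <- sample(c("M", "F"), cfg$n_samples, replace = TRUE)
  ig <- reference$implant_genes
  ad_s <- samples[1]; ar_s <- samples[2]; xl_s <- samples[3]
  sex[3] <- "M"
  ped <- tibble::tibble(
    family_id = paste0("F", sub("^S", "", samples)), sample_id = samples,
    father_id = ifelse(samples %in% c(ad_s, ar_s, xl_s),
                       paste0(samples, "_fa"), "0"),
    mother_id = ifelse(samples %in% c(ad_s, ar_s, xl_s),
                       paste0(samples, "_mo"), "0"),
    sex = sex, affected = TRUE)

  calls <- list(); truth <- list(); obs <- list()
  chr1_genes <- unique(ens$gene_id[ens$chrom == "chr1"])
  ad_idx <- match(ig$ad, chr1_genes)
  flank <- chr1_genes[c(ad_idx - 1, ad_idx, ad_idx + 1)]
  ad_rows <- ens[ens$gene_id %in% flank, ]
  ad_span <- c(start = min(ad_rows$exon_start) - 5000,
               end = max(ad_rows$exon_end) + 5000)
  fragment_ad <- stats::runif(1) < cfg$fragmentation_prob
  if (fragment_ad) {
    k <- sample(seq(cfg$frag_range[1], cfg$frag_range[2]), 1)
    # cut at intergenic gaps so each fragment holds whole genes
    spans <- ens[ens$gene_id %in% flank, ] |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(s = min(.data$exon_start), e = max(.data$exon_end),
                       .groups = "drop") |>
      dplyr::arrange(.data$s)
    k <- min(k, nrow(spans))
    grp <- sort(rep_len(seq_len(k), nrow(spans)))
    frag <- spans |>
      dplyr::mutate(g = grp) |>
      dplyr::group_by(.data$g) |>
      dplyr::summarise(start = min(.data$s) - 1000, end = max(.data$e) + 1000,
                       .groups = "drop")
    calls$ad <- tibble::tibble(sample_id = ad_s, chrom = "chr1",
                               start = frag$start, end = frag$end,
                               svtype = "DEL", cn = 1,
                               qs = round(stats::runif(nrow(frag), 600, 900)))
  } else {
    calls$ad <- tibble::tibble(sample_id = ad_s, chrom = "chr1",
                               start = ad_span[["start"]],
                               end = ad_span[["end"]], svtype = "DEL", cn = 1,
                               qs = round(stats::runif(1, 600, 900)))
  }
  truth$ad <- tibble::tibble(label = "ad_de_novo_del", sample_id = ad_s,
                             chrom = "chr1", start = ad_span[["start"]],
                             end = ad_span[["end"]], svtype = "DEL",
                             n_fragments = nrow(calls$ad),
                             expected_high_confidence = TRUE,
                             expected_classification = "P")
  obs$ad <- tibble::tibble(sample_id = ad_s, gene = ig$ad, zygosity = "het",
                           phase = "unknown", second_variant_class = "none",
                           phenotype_specificity = "none", sex = sex[1],
                           de_novo = "confirmed",
                           maternal_carrier_affected = NA,
                           functional_evidence = "none")

  ar_tx <- ens[ens$gene_id == ig$ar, ]
  win <- pick_ar_window(ar_tx)
  calls$ar <- tibble::tibble(sample_id = ar_s, chrom = "chr1",
                             start = win[["start"]], end = win[["end"]],
                             svtype = "DEL", cn = 1,
                             qs = round(stats::runif(1, 200, 400)))
  truth$ar <- tibble::tibble(label = "ar_compound_het_del", sample_id = ar_s,
                             chrom = "chr1", start = win[["start"]],
                             end = win[["end"]], svtype = "DEL",
                             n_fragments = 1L,
                             expected_high_confidence = TRUE,
                             expected_classification = "P")
  obs$ar <- tibble::tibble(sample_id = ar_s, gene = ig$ar, zygosity = "het",
                           phase = "in_trans_confirmed",
                           second_variant_class = "P",
                           phenotype_specificity = "none", sex = sex[2],
                           de_novo = "unknown",
                           maternal_carrier_affected = NA,
                           functional_evidence = "none")

  xs <- gene_span(gm, ig$xl)
  calls$xl <- tibble::tibble(sample_id = xl_s, chrom = "chrX",
                             start = as.numeric(xs[["start"]]) - 1000,
                             end = as.numeric(xs[["end"]]) + 1000,
                             svtype = "DEL", cn = 0,
                             qs = round(stats::runif(1, 450, 800)))
  truth$xl <- tibble::tibble(label = "xl_hemizygous_del", sample_id = xl_s,
                             chrom = "chrX", start = calls$xl$start,
                             end = calls$xl$end, svtype = "DEL",
                             n_fragments = 1L,
                             expected_high_confidence = TRUE,
                             expected_classification = "P")
  obs$xl <- tibble::tibble(sample_id = xl_s, gene = ig$xl, zygosity = "hemi",
                           phase = "unknown", second_variant_class = "none",
                           phenotype_specificity = "none", sex = "M",
                           de_novo = "confirmed",
                           maternal_carrier_affected = FALSE,
                           functional_evidence = "none")

  bl <- reference$panel[1, ]   # benign implant locus
  n_benign <- round(cfg$benign_carrier_freq * cfg$n_samples)
  benign_samples <- setdiff(samples, c(ad_s, ar_s, xl_s))[seq_len(n_benign)]
  calls$benign <- tibble::tibble(sample_id = benign_samples, chrom = bl$chrom,
                                 start = bl$start, end = bl$end,
                                 svtype = "DEL", cn = 1,
                                 qs = round(stats::runif(n_benign, 120, 300)))
  truth$benign <- tibble::tibble(label = "benign_common_del",
                                 sample_id = benign_samples,
                                 chrom = bl$chrom, start = bl$start,
                                 end = bl$end, svtype = "DEL",
                                 n_fragments = 1L,
                                 expected_high_confidence = FALSE,
                                 expected_classification = NA_character_)

  # exclusion zones: implant loci must stay free of background calls
  excl <- tibble::tibble(
    chrom = c("chr1", "chr1", "chrX", bl$chrom),
    start = c(ad_span[["start"]], win[["start"]], calls$xl$start, bl$start) - 5e4,
    end = c(ad_span[["end"]], win[["end"]], calls$xl$end, bl$end) + 5e4)
  chr1_len <- reference$chrom_len[["chr1"]]
  draw_clear <- function(n, len_min, len_max) {
    out <- NULL
    while (is.null(out) || nrow(out) < n) {
      s <- sample.int(chr1_len - len_max, n)
      l <- sample(len_min:len_max, n, replace = TRUE)
      cand <- tibble::tibble(chrom = "chr1", start = s, end = s + l)
      bad <- unique(interval_overlap_pairs(cand, excl)$x)
      cand <- if (length(bad)) cand[-bad, ] else cand
      out <- dplyr::bind_rows(out, cand)
    }
    out[seq_len(n), ]
  }
  # low-QS artifact calls: keep samples high-quality (<=200 raw calls,
  # >=35 with QS>20) while staying below every analysis gate; short enough
  # (<300 bp) that they can never reach 10% reciprocal overlap with a
  # multi-exon call and inflate its cluster frequency
  noise <- purrr::map_dfr(samples, function(s) {
    n <- cfg$n_noise_calls
    iv <- draw_clear(n, 100, 300)
    dplyr::mutate(iv, sample_id = s,
                  svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
                  qs = c(round(stats::runif(n - 5, 21, 49)),
                         round(stats::runif(5, 2, 19)))) |>
      dplyr::mutate(cn = ifelse(.data$svtype == "DEL", 1, 3))
  })
  # rare incidental high-quality calls, median ~2 per sample: each call
  # occupies a distinct 3-exon window ("slot") so it is unique in the
  # cohort, as real rare CNVs overwhelmingly are
  excl_genes <- c(flank, ig$ar, ig$benign)
  slot_genes <- setdiff(chr1_genes, excl_genes)
  slots <- purrr::map_dfr(slot_genes, function(g) {
    tx <- dplyr::arrange(ens[ens$gene_id == g, ], .data$exon_start)
    k <- nrow(tx)
    starts <- seq(1, k - 2, by = 3)
    tibble::tibble(chrom = tx$chrom[1],
                   start = tx$exon_start[starts] - 200,
                   end = tx$exon_end[starts + 2] + 200)
  })
  n_rare <- pmin(stats::rpois(cfg$n_samples, cfg$rare_benign_rate),
                 nrow(slots) %/% cfg$n_samples + 2)
  if (sum(n_rare) > nrow(slots)) n_rare <- pmin(n_rare, 1)
  slot_idx <- sample.int(nrow(slots), sum(n_rare))
  rare <- slots[slot_idx, ] |>
    dplyr::mutate(sample_id = rep(samples, n_rare),
                  svtype = sample(c("DEL", "DUP"), dplyr::n(), replace = TRUE,
                                  prob = c(0.7, 0.3)),
                  cn = ifelse(.data$svtype == "DEL", 1, 3),
                  qs = round(stats::runif(dplyr::n(), 150, 600)))
  all_calls <- call_cols(dplyr::bind_rows(c(calls, list(noise = noise,
                                                        rare = rare))))
  list(calls = dplyr::arrange(all_calls, .data$sample_id, .data$chrom,
                              .data$start),
       ped = ped,
       observations = dplyr::bind_rows(obs),
       truth = dplyr::bind_rows(truth))
}

#' Write every synthetic artifact to a directory in its exchange format
#'
#' Emits the formats the pipeline reads: calls as SV-VCF and TSV, gene
#' models as GFF3 (one file per source), probes as BED3, panel as BED+2,
#' pedigree as PED, observations as JSON and the truth table as TSV.
#'
#' @param reference Output of [generate_reference()].
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(reference, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments_vcf(cohort$calls, file.path(dir, "calls.vcf"),
                     samples = cohort$ped$sample_id)
  write_segments_tsv(cohort$calls, file.path(dir, "calls.tsv"))
  for (src in unique(reference$gene_models$source_label)) {
    write_gene_model_gff3(
      reference$gene_models[reference$gene_models$source_label == src, ],
      file.path(dir, paste0("genes_", src, ".gff3")))
  }
  write_probes_bed(reference$probes, file.path(dir, "probes.bed"))
  write_panel_bed(reference$panel, file.path(dir, "panel.bed"))
  write_dosage(reference$dosage, file.path(dir, "dosage.tsv"))
  write_ped(cohort$ped, file.path(dir, "cohort.ped"))
  write_observations(cohort$observations, file.path(dir, "observations.json"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
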