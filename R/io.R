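#' Read a gene model (GFF3 or BED12) into an exon-level tibble
#'
#' External formats are 1-based inclusive (GFF3) or already 0-based half-open
#' (BED12); both are converted to the internal 0-based half-open convention.
#' The result has one row per exon with columns `source_label`, `gene_id`,
#' `gene_name`, `transcript_id`, `biotype`, `strand`, `chrom`, `exon_start`,
#' `exon_end`, `cds_start`, `cds_end` (CDS columns `NA` for non-coding
#' transcripts).
#'
#' For BED12 input the thick region encodes the CDS; a transcript whose thick
#' region is empty is classified `other`, otherwise `protein_coding`.
#' Unknown GFF3 biotypes are classified `other` with a warning.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed12"`.
#' @param source_label Label recorded on every row (e.g. `"omim-like"`).
#' @return Exon-level gene model tibble.
#' @export
read_gene_model <- function(path, format = c("gff3", "bed12"),
                            source_label = "default") {
  format <- match.arg(format)
  if (format == "gff3") read_gene_model_gff3(path, source_label)
  else read_gene_model_bed12(path, source_label)
}

known_biotypes <- c("protein_coding", "other")

#' @keywords internal
read_gene_model_gff3 <- function(path, source_label) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  types <- tolower(df$type)
  mrna <- df[types %in% c("mrna", "transcript"), ]
  if (nrow(mrna) == 0) rlang::abort(paste0("no transcripts in GFF3: ", path))
  parent_of <- function(x) vapply(x, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  tx <- tibble::tibble(
    transcript_id = as.character(mrna$ID),
    gene_id = parent_of(mrna$Parent),
    biotype = if ("biotype" %in% names(mrna)) as.character(mrna$biotype)
              else NA_character_
  )
  genes <- df[types == "gene", ]
  gene_name <- stats::setNames(
    if ("Name" %in% names(genes)) as.character(genes$Name) else as.character(genes$ID),
    as.character(genes$ID))
  if (any(!is.na(tx$biotype) & !tx$biotype %in% known_biotypes)) {
    rlang::warn("unknown biotype(s) classified as 'other'")
  }
  tx$biotype <- ifelse(is.na(tx$biotype) | !tx$biotype %in% known_biotypes,
                       "other", tx$biotype)
  exons <- df[types == "exon", ]
  cds <- df[types == "cds", ]
  cds_by_tx <- if (nrow(cds) > 0) {
    dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(transcript_id = parent_of(cds$Parent),
                       s = cds$start - 1, e = cds$end),
        .data$transcript_id),
      cds_start = min(.data$s), cds_end = max(.data$e), .groups = "drop")
  } else {
    tibble::tibble(transcript_id = character(), cds_start = numeric(),
                   cds_end = numeric())
  }
  out <- tibble::tibble(
    transcript_id = parent_of(exons$Parent),
    chrom = norm_chrom(as.character(exons$seqnames)),
    exon_start = exons$start - 1,          # GFF3 is 1-based inclusive
    exon_end = as.numeric(exons$end),
    strand = as.character(exons$strand)
  ) |>
    dplyr::left_join(tx, by = "transcript_id") |>
    dplyr::left_join(cds_by_tx, by = "transcript_id") |>
    dplyr::mutate(
      gene_name = unname(gene_name[.data$gene_id]),
      source_label = source_label
    ) |>
    dplyr::arrange(.data$chrom, .data$gene_id, .data$exon_start)
  gene_model_cols(out)
}

#' @keywords internal
read_gene_model_bed12 <- function(path, source_label) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  rows <- purrr::map_dfr(seq_along(gr), function(i) {
    b <- blocks[[i]]
    tx_start <- GenomicRanges::start(gr)[i] - 1   # back to 0-based
    thick <- gr$thick[i]
    has_cds <- IRanges::width(thick) > 1
    tibble::tibble(
      transcript_id = gr$name[i],
      chrom = norm_chrom(as.character(GenomicRanges::seqnames(gr)[i])),
      # blocks are 1-based relative to the transcript start after import
      exon_start = tx_start + IRanges::start(b) - 1,
      exon_end = tx_start + as.numeric(IRanges::end(b)),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      biotype = if (has_cds) "protein_coding" else "other",
      cds_start = if (has_cds) IRanges::start(thick) - 1 else NA_real_,
      cds_end = if (has_cds) as.numeric(IRanges::end(thick)) else NA_real_
    )
  })
  rows |>
    dplyr::mutate(gene_id = .data$transcript_id,
                  gene_name = .data$transcript_id,
                  source_label = source_label) |>
    dplyr::arrange(.data$chrom, .data$gene_id, .data$exon_start) |>
    gene_model_cols()
}

#' @keywords internal
gene_model_cols <- function(x) {
  dplyr::select(x, "source_label", "gene_id", "gene_name", "transcript_id",
                "biotype", "strand", "chrom", "exon_start", "exon_end",
                "cds_start", "cds_end")
}

#' Write a gene model as GFF3
#'
#' Inverse of [read_gene_model()] for the GFF3 path; round-trips coordinates
#' exactly.
#' @param gm Exon-level gene model tibble.
#' @param path Output path.
#' @export
write_gene_model_gff3 <- function(gm, path) {
  per_tx <- dplyr::summarise(
    dplyr::group_by(gm, .data$gene_id, .data$gene_name, .data$transcript_id,
                    .data$biotype, .data$strand, .data$chrom,
                    .data$cds_start, .data$cds_end),
    tx_start = min(.data$exon_start), tx_end = max(.data$exon_end),
    .groups = "drop")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(per_tx))) {
    t <- per_tx[i, ]
    lines <- c(lines,
      sprintf("%s\tcnvclassr\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              t$chrom, t$tx_start + 1, t$tx_end, t$strand, t$gene_id, t$gene_name),
      sprintf("%s\tcnvclassr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
              t$chrom, t$tx_start + 1, t$tx_end, t$strand, t$transcript_id,
              t$gene_id, t$biotype))
    ex <- gm[gm$transcript_id == t$transcript_id, ]
    lines <- c(lines, sprintf(
      "%s\tcnvclassr\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
      ex$chrom, ex$exon_start + 1, ex$exon_end, ex$strand, ex$transcript_id,
      seq_len(nrow(ex)), ex$transcript_id))
    if (!is.na(t$cds_start)) {
      cds_ex <- ex[ex$exon_end > t$cds_start & ex$exon_start < t$cds_end, ]
      lines <- c(lines, sprintf(
        "%s\tcnvclassr\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
        cds_ex$chrom, pmax(cds_ex$exon_start, t$cds_start) + 1,
        pmin(cds_ex$exon_end, t$cds_end), cds_ex$strand, t$transcript_id,
        seq_len(nrow(cds_ex)), t$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read array probe positions from a BED3 file
#'
#' @param path BED3 file (0-based half-open).
#' @param platform_label Label recorded on the probe set.
#' @return Tibble with `chrom`, `start`, `end`, `platform_label`, sorted by
#'   (chrom, start).
#' @export
read_probes <- function(path, platform_label = "array") {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cdd", comment = "#", progress = FALSE)
  if (any(is.na(bed$start) | is.na(bed$end))) {
    rlang::abort(paste0("malformed BED3 line in ", path))
  }
  bed |>
    dplyr::mutate(chrom = norm_chrom(.data$chrom),
                  platform_label = platform_label) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write probes as BED3
#' @param probes Probe tibble.
#' @param path Output path.
#' @export
write_probes_bed <- function(probes, path) {
  readr::write_tsv(probes[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read per-sample CNV segment calls
#'
#' Two dialects are supported. `sv_vcf`: a structural-variant VCF carrying
#' `SVTYPE` and `END` in INFO and per-sample `CN` (integer copy number) and
#' `QS` (quality score) in FORMAT; one call is produced per record x sample
#' whose CN differs from the ploidy at the locus. `tsv`: a 7-column table
#' `sample_id, chrom, start, end, svtype, cn, qs` with 1-based inclusive
#' coordinates.
#'
#' @param path Input file.
#' @param dialect `"sv_vcf"` or `"tsv"`.
#' @param ped Optional pedigree tibble (see [read_ped()]) used to assign
#'   ploidy 1 on chrX for males; without it ploidy 2 is assumed everywhere.
#' @return Call tibble: `sample_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `svtype`, `cn`, `qs`, `n_exons` (NA until annotated).
#' @export
read_segments <- function(path, dialect = c("sv_vcf", "tsv"), ped = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    x <- readr::read_tsv(path, col_types = "ccddcdd", progress = FALSE)
    stopifnot(all(c("sample_id", "chrom", "start", "end", "svtype", "cn",
                    "qs") %in% names(x)))
    return(call_cols(dplyr::mutate(x, chrom = norm_chrom(.data$chrom),
                                   start = .data$start - 1)))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files drop to vector
  fix <- tibble::as_tibble(fix)
  svtype <- unname(vcfR::extract.info(vcf, "SVTYPE"))
  end <- unname(as.numeric(vcfR::extract.info(vcf, "END")))
  bad <- is.na(svtype) | is.na(end)
  if (any(bad)) {
    rlang::warn(sprintf("%d record(s) missing SVTYPE/END skipped", sum(bad)))
  }
  cn <- vcfR::extract.gt(vcf, element = "CN", as.numeric = TRUE)
  qs <- vcfR::extract.gt(vcf, element = "QS", as.numeric = TRUE)
  samples <- colnames(cn)
  rec <- tibble::tibble(
    chrom = norm_chrom(fix$CHROM),
    start = as.numeric(fix$POS) - 1,   # VCF POS is 1-based
    end = end, svtype = svtype, idx = seq_len(nrow(fix))
  )[!bad, ]
  males <- if (!is.null(ped)) ped$sample_id[ped$sex == "M"] else character()
  out <- purrr::map_dfr(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    cni <- cn[r$idx, ]
    qsi <- qs[r$idx, ]
    keep <- !is.na(cni)
    pl <- ifelse(norm_chrom(r$chrom) == "chrX" & samples %in% males, 1, 2)
    nonref <- keep & cni != pl
    if (any(keep & !nonref)) {
      rlang::warn("genotype(s) with reference copy number skipped")
    }
    if (!any(nonref)) return(NULL)
    tibble::tibble(sample_id = samples[nonref], chrom = r$chrom,
                   start = r$start, end = r$end, svtype = r$svtype,
                   cn = unname(cni[nonref]), qs = unname(qsi[nonref]))
  })
  call_cols(out)
}

#' @keywords internal
call_cols <- function(x) {
  if (is.null(x) || nrow(x) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          svtype = character(), cn = numeric(), qs = numeric(),
                          n_exons = numeric()))
  }
  if (!"n_exons" %in% names(x)) x$n_exons <- NA_real_
  tibble::as_tibble(x)[, c("sample_id", "chrom", "start", "end", "svtype",
                           "cn", "qs", "n_exons")]
}

#' Write calls in the documented SV-VCF dialect
#'
#' One record per (chrom, start, end, svtype) site; per-sample FORMAT fields
#' `CN:QS`, with `.` for samples carrying the reference copy number.
#' @param calls Call tibble.
#' @param path Output path.
#' @param samples Optional full sample list (columns for non-carriers).
#' @export
write_segments_vcf <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  sites <- calls |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$svtype) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$svtype)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
    "##FORMAT=<ID=QS,Number=1,Type=Float,Description=\"Quality score\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    here <- calls[calls$chrom == s$chrom & calls$start == s$start &
                    calls$end == s$end & calls$svtype == s$svtype, ]
    gt <- stats::setNames(rep("./.", length(samples)), samples)
    gt[here$sample_id] <- sprintf("%d:%g", as.integer(here$cn), here$qs)
    paste(c(s$chrom, format(s$start + 1, scientific = FALSE),
            sprintf("%s_%s_%s", s$chrom, format(s$start + 1, scientific = FALSE), s$svtype),
            "N", paste0("<", s$svtype, ">"), ".", ".",
            sprintf("SVTYPE=%s;END=%s", s$svtype,
                    format(s$end, scientific = FALSE)),
            "CN:QS", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write calls as the 7-column TSV dialect (1-based inclusive)
#' @param calls Call tibble.
#' @param path Output path.
#' @export
write_segments_tsv <- function(calls, path) {
  out <- dplyr::mutate(calls[, c("sample_id", "chrom", "start", "end",
                                 "svtype", "cn", "qs")],
                       start = .data$start + 1)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a PED pedigree file
#'
#' Standard 6-column PED: family, sample, father, mother, sex (1=M, 2=F),
#' phenotype (2=affected).
#' @param path PED file.
#' @return Tibble with `family_id`, `sample_id`, `father_id`, `mother_id`,
#'   `sex` ("M"/"F"), `affected` (logical).
#' @export
read_ped <- function(path) {
  x <- readr::read_tsv(path, col_names = c("family_id", "sample_id",
                                           "father_id", "mother_id", "sex",
                                           "phenotype"),
                       col_types = "ccccdd", progress = FALSE)
  dplyr::mutate(x,
                sex = dplyr::if_else(.data$sex == 1, "M", "F"),
                affected = .data$phenotype == 2)
}

#' Write a PED pedigree file
#' @param ped Pedigree tibble as returned by [read_ped()].
#' @param path Output path.
#' @export
write_ped <- function(ped, path) {
  out <- dplyr::mutate(ped,
                       sex = dplyr::if_else(.data$sex == "M", 1, 2),
                       phenotype = dplyr::if_else(.data$affected, 2, 1))
  readr::write_tsv(out[, c("family_id", "sample_id", "father_id", "mother_id",
                           "sex", "phenotype")], path, col_names = FALSE)
  invisible(path)
}

#' Read a population SV panel from a BED+2 file
#'
#' BED3 coordinates plus `svtype` and `af` columns.
#' @param path Panel file.
#' @param panel_label Label recorded on every row.
#' @return Tibble `chrom`, `start`, `end`, `svtype`, `af`, `panel_label`.
#' @export
read_panel <- function(path, panel_label = "panel") {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "svtype",
                                           "af"),
                       col_types = "cddcd", comment = "#", progress = FALSE)
  if (any(x$af < 0 | x$af > 1)) rlang::abort("panel allele frequency outside [0,1]")
  dplyr::arrange(dplyr::mutate(x, chrom = norm_chrom(.data$chrom),
                               panel_label = panel_label),
                 .data$chrom, .data$start)
}

#' Write a population SV panel (BED+2)
#' @param panel Panel tibble.
#' @param path Output path.
#' @export
write_panel_bed <- function(panel, path) {
  readr::write_tsv(panel[, c("chrom", "start", "end", "svtype", "af")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a dosage / disease-gene table
#'
#' TSV with columns `gene`, `moi` (AD/AR/XL), `established`,
#' `haploinsufficient`, `triplosensitive` (logicals).
#' @param path TSV path.
#' @return Dosage tibble.
#' @export
read_dosage <- function(path) {
  readr::read_tsv(path, col_types = "cclll", progress = FALSE)
}

#' Write a dosage table
#' @param dosage Dosage tibble.
#' @param path Output path.
#' @export
write_dosage <- function(dosage, path) {
  readr::write_tsv(dosage, path)
  invisible(path)
}

#' Read / write case observations (JSON)
#'
#' Case observations carry the per-proband evidence consumed by the scoring
#' engine: zygosity, phase, the classification of the second variant, sex,
#' de novo status, carrier-parent affected status, phenotype specificity and
#' functional-evidence level.
#' @param path JSON path.
#' @return Tibble of observations.
#' @export
read_observations <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' @rdname read_observations
#' @param obs Observations tibble.
#' @export
write_observations <- function(obs, path) {
  jsonlite::write_json(obs, path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' Write events as BED (0-based half-open, name = sample:type)
#' @param events Event tibble (see [merge_fragments()]).
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  out <- tibble::tibble(chrom = events$chrom, start = events$start,
                        end = events$end,
                        name = paste0(events$sample_id, ":",
                                      events$resolved_type))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Format an interval in the 1-based inclusive report style
#'
#' E.g. `chr1:197438450-197439442` for an internal half-open interval.
#' @param chrom,start,end Internal 0-based half-open interval.
#' @return Character vector.
#' @export
format_region <- function(chrom, start, end) {
  sprintf("%s:%s-%s", norm_chrom(chrom),
          format(start + 1, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE))
}
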