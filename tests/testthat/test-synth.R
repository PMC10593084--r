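small_cfg <- function(...) synth_config(seed = 11, n_samples = 30,
                                        n_genes = 60, n_noise_calls = 40, ...)

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  c1 <- generate_cohort(r1, cfg)
  c2 <- generate_cohort(r2, cfg)
  expect_identical(c1, c2)
  # different seed changes the data
  r3 <- generate_reference(synth_config(seed = 12, n_samples = 30,
                                        n_genes = 60, n_noise_calls = 40))
  expect_false(identical(r1$probes, r3$probes))
})

test_that("reference honours probe density, panel size and source structure", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  glen <- sum(ref$chrom_len)
  expected <- glen / 1000 * cfg$probe_density
  expect_lt(abs(nrow(ref$probes) - expected), 5 * sqrt(expected))
  expect_equal(nrow(ref$panel), cfg$panel_size)
  expect_true(all(ref$panel$af >= 0 & ref$panel$af <= 1))
  expect_setequal(unique(ref$gene_models$source_label),
                  c("omim-like", "ensembl-like"))
  # curated source is a strict subset of the full source
  n_omim <- dplyr::n_distinct(ref$gene_models$gene_id[
    ref$gene_models$source_label == "omim-like"])
  n_ens <- dplyr::n_distinct(ref$gene_models$gene_id[
    ref$gene_models$source_label == "ensembl-like"])
  expect_lt(n_omim, n_ens)
  # genes never overlap within a source
  per_gene <- ref$gene_models |>
    dplyr::filter(.data$source_label == "ensembl-like") |>
    dplyr::group_by(.data$chrom, .data$gene_id) |>
    dplyr::summarise(s = min(.data$exon_start), e = max(.data$exon_end),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$s)
  gaps <- per_gene |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(prev_end = dplyr::lag(.data$e)) |>
    dplyr::filter(!is.na(.data$prev_end))
  expect_true(all(gaps$s > gaps$prev_end))
})

test_that("cohort carries one truth record per implant at stated frequencies", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  coh <- generate_cohort(ref, cfg)
  expect_equal(sum(coh$truth$label == "ad_de_novo_del"), 1)
  expect_equal(sum(coh$truth$label == "ar_compound_het_del"), 1)
  expect_equal(sum(coh$truth$label == "xl_hemizygous_del"), 1)
  n_benign <- sum(coh$truth$label == "benign_common_del")
  expect_equal(n_benign, round(cfg$benign_carrier_freq * cfg$n_samples))
  # the AD implant carrier frequency in the raw calls is 1/n_samples
  ad <- coh$truth[coh$truth$label == "ad_de_novo_del", ]
  cc <- cluster_alleles(coh$calls, n_samples = cfg$n_samples, ped = coh$ped)
  ad_calls <- cc[cc$sample_id == ad$sample_id & cc$chrom == ad$chrom &
                   cc$start >= ad$start & cc$end <= ad$end, ]
  expect_equal(unique(ad_calls$frequency), 1 / cfg$n_samples)
})

test_that("fragmentation emits the large implant as multiple mergeable calls", {
  cfg <- small_cfg(fragmentation_prob = 1)
  ref <- generate_reference(cfg)
  coh <- generate_cohort(ref, cfg)
  ad <- coh$truth[coh$truth$label == "ad_de_novo_del", ]
  expect_gte(ad$n_fragments, 2)
  frags <- coh$calls[coh$calls$sample_id == ad$sample_id &
                       coh$calls$chrom == ad$chrom &
                       coh$calls$start >= ad$start &
                       coh$calls$end <= ad$end, ]
  expect_equal(nrow(frags), ad$n_fragments)
  whole <- synth_config(seed = 11, n_samples = 30, n_genes = 60,
                        n_noise_calls = 40, fragmentation_prob = 0)
  coh0 <- generate_cohort(generate_reference(whole), whole)
  expect_equal(coh0$truth$n_fragments[coh0$truth$label == "ad_de_novo_del"],
               1L)
})

test_that("the common benign implant is removed by the MOI frequency filters", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  coh <- generate_cohort(ref, cfg)
  cc <- cluster_alleles(coh$calls, n_samples = cfg$n_samples, ped = coh$ped)
  benign <- coh$truth[coh$truth$label == "benign_common_del", ][1, ]
  is_benign <- cc$chrom == benign$chrom & cc$start == benign$start
  expect_true(any(is_benign))
  dom <- filter_by_moi(cc, "dominant")
  rec <- filter_by_moi(cc, "recessive")
  expect_false(any(dom$start == benign$start & dom$chrom == benign$chrom))
  expect_false(any(rec$start == benign$start & rec$chrom == benign$chrom))
})

test_that("every exchange format written by the bundle reads back", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  coh <- generate_cohort(ref, cfg)
  dir <- withr::local_tempdir()
  write_synth_bundle(ref, coh, dir)
  vcf <- read_segments(file.path(dir, "calls.vcf"), "sv_vcf", ped = coh$ped)
  tsv <- read_segments(file.path(dir, "calls.tsv"), "tsv")
  expect_equal(nrow(vcf), nrow(coh$calls))
  expect_equal(nrow(tsv), nrow(coh$calls))
  key <- function(x) paste(x$sample_id, x$chrom, x$start, x$end, x$svtype)
  expect_setequal(key(vcf), key(coh$calls))
  gm <- read_gene_model(file.path(dir, "genes_omim-like.gff3"), "gff3",
                        source_label = "omim-like")
  orig <- ref$gene_models[ref$gene_models$source_label == "omim-like", ]
  expect_equal(nrow(gm), nrow(orig))
  expect_setequal(gm$exon_start, orig$exon_start)
  expect_equal(nrow(read_probes(file.path(dir, "probes.bed"))),
               nrow(ref$probes))
  expect_equal(nrow(read_panel(file.path(dir, "panel.bed"))),
               nrow(ref$panel))
  expect_equal(read_ped(file.path(dir, "cohort.ped"))$sample_id,
               coh$ped$sample_id)
  expect_equal(nrow(read_observations(file.path(dir, "observations.json"))),
               nrow(coh$observations))
})
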