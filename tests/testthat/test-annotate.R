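test_that("exon-count annotation fills n_exons from the gene model", {
  gm <- make_tx(5)
  calls <- dplyr::bind_rows(
    make_call(start = gm$exon_start[1], end = gm$exon_end[3]),
    make_call(start = gm$exon_end[5] + 100, end = gm$exon_end[5] + 200))
  out <- annotate_exon_counts(calls, gm)
  expect_equal(out$n_exons, c(3, 0))
})

test_that("gene content counts protein-coding genes per source", {
  gm <- dplyr::bind_rows(
    make_tx(3, offset = 1e3, gene_id = "A"),
    make_tx(3, offset = 2e4, gene_id = "B"),
    make_tx(3, offset = 4e4, gene_id = "C"),
    make_tx(3, offset = 6e4, gene_id = "N1", biotype = "other"),
    make_tx(3, offset = 8e4, gene_id = "N2", biotype = "other"))
  ev <- merge_fragments(make_call(start = 0, end = 1e5))
  ann <- annotate_gene_content(ev, gm)
  expect_equal(ann$n_genes, 3L)
  expect_false(ann$discordant_sources)
  expect_setequal(ann$genes[[1]], c("A", "B", "C"))
})

test_that("single-exon deletion inside one gene is intragenic with exon count 1", {
  gm <- make_tx(8, gene_id = "RETG1")
  ev <- merge_fragments(make_call(start = gm$exon_start[4] - 50,
                                  end = gm$exon_end[4] + 50, cn = 0,
                                  qs = 120))
  ann <- annotate_gene_content(ev, gm)
  expect_true(ann$intragenic)
  expect_equal(unname(ann$exon_counts[[1]]["RETG1"]), 1L)
  expect_equal(ann$n_genes, 1L)
})

test_that("gene-count sources can disagree; conservative minimum is used", {
  curated <- purrr::map_dfr(1:28, ~ make_tx(
    2, offset = .x * 2e4, gene_id = sprintf("g%02d", .x),
    source_label = "omim-like"))
  browser_src <- purrr::map_dfr(1:35, ~ make_tx(
    2, offset = .x * 2e4, gene_id = sprintf("g%02d", .x),
    source_label = "ensembl-like"))
  gm <- dplyr::bind_rows(curated, browser_src)
  ev <- merge_fragments(make_call(start = 0, end = 1e6, svtype = "DUP",
                                  cn = 3))
  ann <- annotate_gene_content(ev, gm)
  expect_true(ann$discordant_sources)
  expect_equal(ann$gene_counts[[1]][["omim-like"]], 28L)
  expect_equal(ann$gene_counts[[1]][["ensembl-like"]], 35L)
  expect_equal(ann$n_genes, 28L)
  pinned <- annotate_gene_content(ev, gm, count_source = "ensembl-like")
  expect_equal(pinned$n_genes, 35L)
})

test_that("an event containing exactly its own gene counts 1 gene", {
  gm <- make_tx(4, gene_id = "solo")
  ev <- merge_fragments(make_call(start = min(gm$exon_start) - 10,
                                  end = max(gm$exon_end) + 10))
  expect_equal(annotate_gene_content(ev, gm)$n_genes, 1L)
})

test_that("population matching applies the size-dependent reciprocal-overlap rule", {
  ev10k <- merge_fragments(make_call(start = 0, end = 1e4))
  ident <- tibble::tibble(chrom = "chr1", start = 0, end = 1e4,
                          svtype = "DEL", af = 0.002, panel_label = "p")
  m <- match_population_sv(ev10k, ident)
  expect_equal(m$pop_n_matches, 1L)
  expect_equal(m$pop_max_af, 0.002)

  # 0.49 reciprocal overlap between two 10-kb deletions: below 50%
  shifted <- dplyr::mutate(ident, start = 5100, end = 15100)
  expect_equal(match_population_sv(ev10k, shifted)$pop_n_matches, 0L)
  expect_equal(match_population_sv(ev10k, shifted)$pop_max_af, 0)

  # small SVs only need 10%
  ev2k <- merge_fragments(make_call(start = 0, end = 2000))
  small <- tibble::tibble(chrom = "chr1", start = 1700, end = 3700,
                          svtype = "DEL", af = 0.01, panel_label = "p")
  expect_equal(match_population_sv(ev2k, small)$pop_n_matches, 1L)

  # type mismatch never matches
  dup <- dplyr::mutate(ident, svtype = "DUP")
  expect_equal(match_population_sv(ev10k, dup)$pop_n_matches, 0L)
})

test_that("population matching agrees with an all-pairs brute-force oracle", {
  set.seed(13)
  panel <- tibble::tibble(
    chrom = "chr1", start = sample.int(2e5, 500, replace = TRUE),
    svtype = sample(c("DEL", "DUP"), 500, replace = TRUE),
    panel_label = "p")
  panel$end <- panel$start + sample(c(800, 4000, 9000, 30000), 500,
                                    replace = TRUE)
  panel$af <- runif(500)
  events <- merge_fragments(purrr::map_dfr(1:40, function(i) {
    s <- sample.int(2e5, 1)
    make_call(sample_id = paste0("s", i), start = s,
              end = s + sample(c(1000, 6000, 20000), 1),
              svtype = sample(c("DEL", "DUP"), 1))
  }))
  got <- match_population_sv(events, panel)
  for (i in seq_len(nrow(events))) {
    ro <- vapply(seq_len(nrow(panel)), function(j) {
      if (events$resolved_type[i] != panel$svtype[j]) return(-1)
      ro_bruteforce(events$start[i], events$end[i], panel$start[j],
                    panel$end[j])
    }, numeric(1))
    thr <- ifelse(events$end[i] - events$start[i] > 5000 &
                    panel$end - panel$start > 5000, 0.5, 0.1)
    hits <- which(ro >= thr & ro > 0)
    expect_equal(got$pop_n_matches[i], length(hits))
    expect_equal(got$pop_max_af[i],
                 if (length(hits)) max(panel$af[hits]) else 0)
  }
})

test_that("microarray detectability requires five probes within the span", {
  probes <- tibble::tibble(chrom = "chr1", start = seq(1000, 9000, 2000),
                           end = seq(1000, 9000, 2000) + 60)
  ev5 <- merge_fragments(make_call(start = 500, end = 9500))
  expect_true(cma_detectable(ev5, probes)$cma_detectable)
  expect_equal(cma_detectable(ev5, probes)$n_probes, 5L)
  ev4 <- merge_fragments(make_call(start = 500, end = 8000))
  expect_false(cma_detectable(ev4, probes)$cma_detectable)
  ev0 <- merge_fragments(make_call(start = 5e5, end = 6e5))
  expect_false(cma_detectable(ev0, probes)$cma_detectable)
})

test_that("score threshold metrics compute rates, medians, and monotone behaviour", {
  m <- threshold_metrics(c(0.8, 0.9, 0.2), c(TRUE, TRUE, TRUE), 0.37)
  expect_equal(m$tpr, 2 / 3)
  expect_true(is.na(m$fpr))
  m2 <- threshold_metrics(c(0.8, 0.1, 0.2, 0.3), c(TRUE, FALSE, FALSE, FALSE),
                          0.37)
  expect_equal(m2$fpr, 0)
  expect_equal(m2$median_noncausal, 0.2)
  set.seed(21)
  scores <- runif(200)
  causal <- runif(200) < 0.3
  cuts <- seq(0.1, 0.9, 0.1)
  mm <- purrr::map_dfr(cuts, ~ threshold_metrics(scores, causal, .x))
  expect_true(all(diff(mm$tpr) <= 0))
  expect_true(all(diff(mm$fpr) <= 0))
  expect_true(all(mm$tpr >= 0 & mm$tpr <= 1))
})
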