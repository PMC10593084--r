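test_that("strength tiers map onto the 0.90/0.45/0.30/0.15 point ladder", {
  expect_equal(strength_to_points("PVS1"), 0.90)
  expect_equal(strength_to_points("strong"), 0.45)
  expect_equal(strength_to_points("moderate"), 0.30)
  expect_equal(strength_to_points("supporting"), 0.15)
  expect_equal(strength_to_points("none"), 0)
  expect_error(strength_to_points("huge"), "strength")
})

test_that("gene-number rule reproduces the printed bins for loss and gain", {
  expect_equal(score_gene_number("DEL", 30)$points, 0.45)
  expect_equal(score_gene_number("DEL", 10)$points, 0)
  expect_equal(score_gene_number("DEL", 24)$points, 0)
  expect_equal(score_gene_number("DEL", 25)$points, 0.45)
  expect_equal(score_gene_number("DEL", 34)$points, 0.45)
  expect_equal(score_gene_number("DEL", 35)$points, 0.90)
  expect_equal(score_gene_number("DUP", 40)$points, 0.45)
  expect_equal(score_gene_number("DUP", 34)$points, 0)
  expect_equal(score_gene_number("DUP", 35)$points, 0.45)
  expect_equal(score_gene_number("DUP", 50)$points, 0.90)
  expect_equal(score_gene_number("DUP", 120)$points, 0.90)
  expect_error(score_gene_number("DEL", -1), "negative")
})

obs_row <- function(zygosity = "het", phase = "unknown",
                    second = "none", pheno = "none", sex = "F",
                    de_novo = "unknown", func = "none") {
  tibble::tibble(sample_id = "p", gene = "G", zygosity = zygosity,
                 phase = phase, second_variant_class = second,
                 phenotype_specificity = pheno, sex = sex,
                 de_novo = de_novo, maternal_carrier_affected = NA,
                 functional_evidence = func)
}

test_that("AR case table scores phase and second-variant class per proband", {
  ar_pts <- function(obs) {
    it <- score_ar_cases(obs)
    it$points[it$category == "4-AR-case"]
  }
  expect_equal(ar_pts(obs_row(phase = "in_trans_confirmed", second = "P")),
               0.30)
  expect_equal(ar_pts(obs_row(phase = "in_trans_confirmed", second = "LP")),
               0.30)
  expect_equal(ar_pts(obs_row(phase = "unknown", second = "P")), 0.15)
  expect_equal(ar_pts(obs_row(phase = "unknown", second = "LP")), 0.08)
  expect_equal(ar_pts(obs_row(zygosity = "hom")), 0.15)
  expect_equal(ar_pts(obs_row(phase = "in_trans_confirmed", second = "VUS")),
               0.08)
  expect_equal(ar_pts(obs_row(phase = "unknown", second = "VUS")), 0)
  expect_equal(ar_pts(obs_row(phase = "in_cis", second = "P")), 0)
})

test_that("AR aggregation caps homozygous, VUS and total case evidence", {
  three_hom <- dplyr::bind_rows(purrr::map(1:3, ~ obs_row(zygosity = "hom")))
  it <- score_ar_cases(three_hom)
  expect_equal(it$points[it$category == "4-AR-case"], 0.30)
  expect_true(it$cap_applied[it$category == "4-AR-case"])

  five_vus <- dplyr::bind_rows(purrr::map(
    1:5, ~ obs_row(phase = "in_trans_confirmed", second = "VUS")))
  expect_equal(score_ar_cases(five_vus)$points[1], 0.16)

  many <- dplyr::bind_rows(purrr::map(
    1:6, ~ obs_row(phase = "in_trans_confirmed", second = "P")))
  expect_equal(score_ar_cases(many)$points[1], 0.90)
})

test_that("phenotype bonus applies once per variant at 0.15 or 0.30", {
  two_unique <- dplyr::bind_rows(obs_row(pheno = "unique"),
                                 obs_row(pheno = "unique"))
  it <- score_phenotype(two_unique)
  expect_equal(nrow(it), 1)
  expect_equal(it$points, 0.15)
  expect_equal(score_phenotype(obs_row(pheno = "unique_strong"))$points, 0.30)
  expect_equal(nrow(score_phenotype(obs_row(pheno = "none"))), 0)
  # inside the AR path the bonus is still a single extra line
  ar <- score_ar_cases(dplyr::bind_rows(
    obs_row(phase = "in_trans_confirmed", second = "P", pheno = "unique"),
    obs_row(phase = "in_trans_confirmed", second = "P", pheno = "unique")))
  expect_equal(sum(ar$category == "PP4-like"), 1)
  expect_equal(ar$points[ar$category == "PP4-like"], 0.15)
})

test_that("XL cases score from the configured table with a 0.45 per-case bound", {
  sch <- scoring_scheme()
  one <- score_xl_cases(obs_row(sex = "M", de_novo = "confirmed"))
  expect_equal(one$points, unname(sch$xl_table[["M.confirmed"]]))
  upgraded <- score_xl_cases(obs_row(sex = "M", de_novo = "confirmed",
                                     pheno = "unique_strong"))
  expect_equal(upgraded$points, 0.45)   # 0.30 + 0.30 bounded at 0.45
  cis <- score_xl_cases(obs_row(sex = "M", de_novo = "confirmed",
                                phase = "in_cis"))
  expect_equal(cis$points, 0)
  expect_error(score_xl_cases(obs_row(sex = NA_character_)), "sex")
})

test_that("de novo and functional evidence score at their configured levels", {
  expect_equal(score_de_novo("confirmed")$points, 0.45)
  expect_equal(score_de_novo("assumed")$points, 0.30)
  expect_equal(nrow(score_de_novo("unknown")), 0)
  expect_error(score_de_novo("maybe"))
  expect_equal(score_functional("strong")$points, 0.45)
  expect_equal(score_functional("moderate")$points, 0.30)
  expect_equal(score_functional("supporting")$points, 0.15)
  expect_equal(nrow(score_functional("none")), 0)
})

test_that("aggregation sums points into the five-tier ranges", {
  dn <- score_de_novo("confirmed")
  expect_equal(aggregate_evidence(dn)$classification, "VUS")
  both <- dplyr::bind_rows(
    tibble::tibble(category = "2E-PVS1", points = 0.90,
                   strength_label = "PVS1", rationale = NA, cap_applied = FALSE),
    tibble::tibble(category = "4-AR-case", points = 0.30,
                   strength_label = NA, rationale = NA, cap_applied = FALSE))
  r <- aggregate_evidence(both)
  expect_equal(r$total, 1.20)
  expect_equal(r$classification, "P")
  expect_equal(aggregate_evidence(both[0, ])$classification, "VUS")
  mk <- function(p) tibble::tibble(category = "x", points = p,
                                   strength_label = NA, rationale = NA,
                                   cap_applied = FALSE)
  expect_equal(aggregate_evidence(mk(0.90))$classification, "LP")
  expect_equal(aggregate_evidence(mk(0.99))$classification, "P")
  expect_equal(aggregate_evidence(mk(-0.90))$classification, "LB")
  expect_equal(aggregate_evidence(mk(-0.99))$classification, "B")
  expect_error(scoring_scheme(ranges = c(P = 0.8, LP = 0.9, LB = -0.9,
                                         B = -0.99)))
})

test_that("adding nonnegative evidence never lowers the classification tier", {
  tiers <- c("B", "LB", "VUS", "LP", "P")
  set.seed(31)
  for (i in 1:100) {
    pts <- runif(sample(1:5, 1), -0.5, 0.6)
    items <- tibble::tibble(category = "x", points = pts,
                            strength_label = NA, rationale = NA,
                            cap_applied = FALSE)
    before <- aggregate_evidence(items)$classification
    extra <- tibble::tibble(category = "y", points = runif(1, 0, 0.9),
                            strength_label = NA, rationale = NA,
                            cap_applied = FALSE)
    after <- aggregate_evidence(dplyr::bind_rows(items, extra))$classification
    expect_gte(match(after, tiers), match(before, tiers))
  }
})

test_that("complex events take the most deleterious component classification", {
  mk <- function(cls, pts) aggregate_evidence(tibble::tibble(
    category = "x", points = pts, strength_label = NA, rationale = NA,
    cap_applied = FALSE))
  p <- mk("P", 1.2); v <- mk("VUS", 0.3); lb <- mk("LB", -0.93)
  lp <- mk("LP", 0.92)
  expect_equal(classify_complex(list(p, v))$classification, "P")
  expect_equal(classify_complex(list(v, v))$classification, "VUS")
  expect_equal(classify_complex(list(lb, lp))$classification, "LP")
  # order independence and associativity
  expect_equal(classify_complex(list(v, lb, p))$classification,
               classify_complex(list(p, lb, v))$classification)
  nested <- classify_complex(list(classify_complex(list(v, lb)), p))
  expect_equal(nested$classification,
               classify_complex(list(v, lb, p))$classification)
  expect_error(classify_complex(list()), "component")
})

test_that("LoF decision tree: frameshift with predicted NMD reaches PVS1", {
  tx <- make_tx(8, exon_len = 151)
  # single internal exon, out of frame, far upstream of the NMD boundary
  s <- pvs1_strength("chr1", tx$exon_start[3] - 50, tx$exon_end[3] + 50,
                     "DEL", tx)
  expect_equal(s, "PVS1")
  # whole-transcript removal
  expect_equal(pvs1_strength("chr1", 0, max(tx$exon_end) + 1e4, "DEL", tx),
               "PVS1")
  expect_error(pvs1_strength("chr1", 0, 1e5, "DEL", tx, established = FALSE),
               "case-evidence")
})

test_that("LoF decision tree: NMD escape and small removals downgrade", {
  tx <- make_tx(8, exon_len = 151)
  # last two exons removed: escapes NMD, >10% of CDS -> strong
  s <- pvs1_strength("chr1", tx$exon_start[7] - 50, tx$exon_end[8] + 50,
                     "DEL", tx)
  expect_equal(s, "strong")
  # in-frame whole internal exon, small fraction -> moderate
  tx15 <- make_tx(15, exon_len = 150)
  expect_equal(pvs1_strength("chr1", tx15$exon_start[3] - 10,
                             tx15$exon_end[3] + 10, "DEL", tx15), "moderate")
  # in-frame partial-exon nibble -> supporting
  expect_equal(pvs1_strength("chr1", tx15$exon_start[3] + 10,
                             tx15$exon_start[3] + 70, "DEL", tx15),
               "supporting")
  # intronic deletion removes no CDS -> none
  expect_equal(pvs1_strength("chr1", tx15$exon_end[3] + 100,
                             tx15$exon_start[4] - 100, "DEL", tx15), "none")
})

test_that("LoF decision tree handles minus-strand transcripts", {
  tx <- make_tx(8, exon_len = 151, strand = "-")
  # genomic exon 5 is transcript-internal; frameshift upstream of the last
  # junction (transcript 3' end is the genomic-first exon)
  s <- pvs1_strength("chr1", tx$exon_start[5] - 20, tx$exon_end[5] + 20,
                     "DEL", tx)
  expect_equal(s, "PVS1")
})

test_that("LoF rules for inversions, insertions and duplications", {
  tx <- make_tx(8, exon_len = 151)
  gene_start <- min(tx$exon_start); gene_end <- max(tx$exon_end)
  # both breakpoints outside the gene, fully containing it: not LoF
  expect_equal(pvs1_strength("chr1", gene_start - 1e4, gene_end + 1e4,
                             "INV", tx), "none")
  # one breakpoint inside the gene: LoF-eligible
  expect_true(pvs1_strength("chr1", tx$exon_start[4], gene_end + 1e4,
                            "INV", tx) != "none")
  # both inside spanning an exon: eligible
  expect_true(pvs1_strength("chr1", tx$exon_start[2] - 10,
                            tx$exon_end[3] + 10, "INV", tx) != "none")
  # both inside, strictly intronic span: not eligible
  expect_equal(pvs1_strength("chr1", tx$exon_end[2] + 10,
                             tx$exon_start[3] - 10, "INV", tx), "none")
  # insertion within a coding exon: eligible
  expect_true(pvs1_strength("chr1", tx$exon_start[3] + 5,
                            tx$exon_start[3] + 6, "INS", tx) != "none")
  # insertion in an intron: not eligible
  expect_equal(pvs1_strength("chr1", tx$exon_end[3] + 50,
                             tx$exon_end[3] + 51, "INS", tx), "none")
  # duplications default to no LoF unless flagged disruptive
  expect_equal(pvs1_strength("chr1", tx$exon_start[2], tx$exon_end[3],
                             "DUP", tx), "none")
  expect_true(pvs1_strength("chr1", tx$exon_start[2], tx$exon_end[3],
                            "DUP", tx, dup_disruptive = TRUE) != "none")
})

test_that("a de novo duplication moves from VUS to at least LP as the gene count grows", {
  with28 <- aggregate_evidence(dplyr::bind_rows(
    score_de_novo("confirmed"), score_gene_number("DUP", 28)))
  with35 <- aggregate_evidence(dplyr::bind_rows(
    score_de_novo("confirmed"), score_gene_number("DUP", 35)))
  expect_equal(with28$classification, "VUS")
  expect_true(with35$classification %in% c("LP", "P"))
})

test_that("tidy, glance and autoplot expose classification results", {
  r <- aggregate_evidence(dplyr::bind_rows(score_de_novo("confirmed"),
                                           score_gene_number("DEL", 30)),
                          event_id = "ev1")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  g <- glance(r)
  expect_equal(g$total, 0.90)
  expect_equal(g$classification, "LP")
  expect_s3_class(autoplot(r), "ggplot")
  expect_output(print(r), "LP")
})
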