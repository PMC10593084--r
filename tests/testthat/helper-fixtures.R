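# Small builders and independent brute-force oracles used across tests.

make_call <- function(sample_id = "S1", chrom = "chr1", start = 0, end = 1e4,
                      svtype = "DEL", cn = 1, qs = 500, n_exons = NA_real_) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, svtype = svtype, cn = cn, qs = qs,
                 n_exons = n_exons)
}

# a transcript with n equal-length exons on one strand
make_tx <- function(n_exons = 5, exon_len = 150, intron_len = 1000,
                    chrom = "chr1", offset = 1000, strand = "+",
                    gene_id = "G1", biotype = "protein_coding",
                    cds_trim = 20, source_label = "src") {
  starts <- offset + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  tibble::tibble(source_label = source_label, gene_id = gene_id,
                 gene_name = gene_id,
                 transcript_id = paste0(gene_id, ".t1"), biotype = biotype,
                 strand = strand, chrom = chrom, exon_start = starts,
                 exon_end = starts + exon_len,
                 cds_start = starts[1] + cds_trim,
                 cds_end = starts[n_exons] + exon_len - cds_trim)
}

# per-base brute-force reciprocal overlap
ro_bruteforce <- function(s1, e1, s2, e2) {
  a <- seq(s1, e1 - 1)
  b <- seq(s2, e2 - 1)
  ov <- length(intersect(a, b))
  min(ov / length(a), ov / length(b))
}

# linear-scan probe counting oracle
probe_count_bruteforce <- function(chrom, start, end, probes) {
  p <- probes[probes$chrom == chrom, ]
  sum(!duplicated(p$start) & p$start >= start & p$start < end)
}

# O(n^2) transitive-closure clustering oracle over the same-allele rule
cluster_bruteforce <- function(calls) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    if (calls$svtype[i] != calls$svtype[j]) next
    if (calls$chrom[i] != calls$chrom[j]) next
    ov <- max(0, min(calls$end[i], calls$end[j]) -
                   max(calls$start[i], calls$start[j]))
    li <- calls$end[i] - calls$start[i]
    lj <- calls$end[j] - calls$start[j]
    ro <- min(ov / li, ov / lj)
    thr <- if (li > 5000 && lj > 5000) 0.50 else 0.10
    adj[i, j] <- ro >= thr
  }
  # transitive closure (Warshall)
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ])
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  comp
}

synth_small <- function(seed = 11, ...) {
  cfg <- synth_config(seed = seed, ...)
  ref <- generate_reference(cfg)
  list(cfg = cfg, ref = ref, cohort = generate_cohort(ref, cfg))
}

# memoised full-cohort pipeline runs shared between test blocks
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(seed = 42, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cfg <- synth_config(seed = seed, ...)
  ref <- generate_reference(cfg)
  coh <- generate_cohort(ref, cfg)
  res <- run_pipeline(coh$calls, ref$gene_models, dosage = ref$dosage,
                      probes = ref$probes, panel = ref$panel,
                      observations = coh$observations, ped = coh$ped)
  .run_cache[[key]] <- list(cfg = cfg, ref = ref, coh = coh, res = res)
  .run_cache[[key]]
}
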