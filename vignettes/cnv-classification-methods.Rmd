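---
title: "Methods: exome CNV filtering, event assembly and quantitative classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exome CNV filtering, event assembly and quantitative classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvclassr)
library(dplyr)
```

## Scope and model

`cnvclassr` operates downstream of a read-depth CNV caller. Its input is a
table of per-sample segment calls — an interval, an SV type (DEL/DUP), an
integer copy number and a caller quality score (QS) — plus reference
resources: one or more exon-resolved gene models, array probe positions, a
population SV panel with allele frequencies, a dosage/disease-gene table,
and per-proband case observations. Its output is a set of per-sample
biological events, each carrying annotation and a five-tier pathogenicity
classification (B/LB/VUS/LP/P) derived from an explicit, fully configurable
point scheme.

Internally all coordinates are 0-based half-open; 1-based formats (GFF3,
VCF, the TSV call dialect) are converted at the I/O boundary, and reports
format regions 1-based inclusive (`chr1:197438450-197439442`). Chromosome
names are normalized to the `chr`-prefixed dialect on read.

## Filtering

Four screens reflect how exome CNV callsets are cleaned in practice:

* **QS gates** (`qs_thresholds()`): duplications pass at QS ≥ 50,
  heterozygous deletions at ≥ 100, homozygous deletions (DEL with copy
  number 0) at ≥ 400. The caller's shorthand "QS>50" coexists in common
  usage with "equal or greater than the threshold"; the engine uses ≥,
  and the thresholds are configurable. An analysis mode with the QS screen
  removed (`run_pipeline(apply_qs = FALSE)`) exists because genuinely
  causal calls — especially 1–2-exon events — can sit below the gates.
* **Per-sample QC** (`sample_qc()`): a sample is high-quality with ≤ 200
  autosomal raw calls of which ≥ 35 have QS > 20 (strictly greater, as
  printed). Too many calls indicate a noisy profile; too few above QS 20
  indicate the caller's model fit poorly.
* **High-confidence flag** (`flag_high_confidence()`): high-quality sample
  AND cluster carrier frequency ≤ 0.01 AND ≥ 3 overlapped exons AND the QS
  gate. The frequency here is the *sample* (carrier) frequency of the
  clustered allele; we compute it after same-allele clustering, since the
  equivalent calls in different samples rarely have identical breakpoints.
* **Mode-of-inheritance frequency screens** (`filter_by_moi()`): strict
  `<` 0.1% for dominant and `<` 1% for recessive analyses. These are
  *allele* frequencies: deletions contribute `2 − CN` alleles per carrier
  (capped to 1..2), duplications one (a copy number alone cannot resolve
  multi-allelic gains), and hemizygous male sex-chromosome calls one when
  a pedigree is available; the denominator is `2 × n_samples`. Keeping
  carrier and allele frequency as distinct quantities matters at desk
  scale: in a 100-sample cohort a singleton heterozygous call has carrier
  frequency 0.01 (on the high-confidence boundary) but allele frequency
  0.005 (clearly below the recessive limit). The cohort-level screen in
  `run_pipeline()` defaults to the permissive recessive limit; the
  dominant limit is meaningful only with denominators in the thousands and
  is applied in family-specific dominant analyses.

Same-allele matching — both for in-cohort clustering and population-panel
lookup — requires the same SV type and reciprocal overlap
`min(ov/len_a, ov/len_b)` of at least 50% when both SVs exceed 5 kb and 10%
otherwise. A pair mixing size classes gets the permissive 10% threshold,
since the size rule is stated per size class without defining mixed pairs.
Clustering is single linkage: candidate pairs come from an interval-overlap
query and connected components of the link graph equal the transitive
closure of the pairwise rule (verified against an O(n²) closure oracle in
the tests).

## Event assembly

Read-depth callers fragment large CNVs. `merge_fragments()` merges
same-sample, same-chromosome, same-type calls whose gap is at most
`max_gap_bp` (default 1 Mb), unless a call of the opposite type overlaps
the gap. The published practice is manual review of the copy-number plot;
no algorithm is stated, so the package uses this conservative, reproducible
rule and exposes the gap. The merge is transitive, order-independent and
idempotent.

`flag_complex_candidate()` marks suspected complex SVs: within one sample
and chromosome, pairs of events within `window_bp` (default 2 Mb) whose
types differ (del/dup patterns), or paired duplications flanking a gap. No
quantitative criterion separates a true complex rearrangement from
coincidental nearby calls, so this window is an explicit heuristic; flagged
events retain their component types and final resolution is expected from
validation. `resolve_with_validation()` replaces the called type with the
validated one (e.g. a recurrent mobile-element insertion miscalled as a
deletion) and adopts refined breakpoints.

## Annotation

Gene-model sources disagree routinely; `annotate_gene_content()` counts
protein-coding genes per source, flags discordance, and scores by the most
conservative (smallest) count by default — curated sources undercount and
browser-derived sources overcount, and a conservative choice avoids
inflating gene-number evidence. The source can be pinned per run. Probes
are treated as point assays at their BED start (a probe "within" a CNV
means `start ∈ [start, end)`): whether a boundary-straddling probe counts
is unstated in array practice, and the point convention makes the count
unambiguous. Microarray detectability requires ≥ 5 probes; complex events
are assessed on their union span. Deleteriousness scores (e.g. a 0–1
SV predictor) are ingested as annotations, never computed;
`threshold_metrics()` evaluates a cutoff with the strict `>` comparison
such scores use.

## The point engine

All constants live in `scoring_scheme()`; the engine itself only sums
capped evidence items and reads the tier off configured ranges
(P ≥ 0.99, LP ≥ 0.90, LB ≤ −0.90, B ≤ −0.99, VUS between).

* **Category 2 / PVS1** (`pvs1_strength()`): for events in genes with an
  established gene-disease relationship. Eligibility — deletions always;
  insertions landing in an exon; inversions with exactly one breakpoint in
  the gene, or both in the gene spanning ≥ 1 exon; duplications only when
  explicitly flagged as intragenic frame-disrupting. Strength —
  whole-transcript removal or a frameshift predicted to trigger
  nonsense-mediated decay is very strong (0.90); NMD prediction uses the
  50-nt rule on the supplied transcript, strand-aware, with the premature
  termination point approximated at the coding offset of the disruption
  junction. Changes escaping NMD but removing > 10% of the coding sequence
  are strong (0.45); a whole in-frame exon is moderate (0.30); a partial
  in-frame nibble is supporting (0.15). When an autosomal-dominant
  established haploinsufficient gene (triplosensitive for gains) is
  completely contained in the event, category-2 established-region points
  (default 1.0, configurable — this value is a framework default, not a
  printed constant) replace the PVS1 path.
* **Gene number (section 3)**: deletions 0 / 0.45 / 0.90 at 0–24 / 25–34 /
  ≥ 35 genes; gains 0 / 0.45 / 0.90 at 0–34 / 35–49 / ≥ 50. The printed
  bins leave exactly-35 (deletion) and exactly-50 (gain) unassigned; they
  are placed in the 0.90 bin to keep the bins contiguous, and the bins are
  configurable.
* **Recessive case evidence** (`score_ar_cases()`): the PM3-style table —
  per proband, 0.30 confirmed in trans with a P or LP second variant; 0.15
  (P) / 0.08 (LP) phase unknown; homozygous 0.15 with aggregate cap 0.30;
  VUS in trans 0.08 with aggregate cap 0.16 and phase-unknown VUS 0;
  in-cis observations score 0. The aggregate case cap defaults to 0.90
  (one "very strong" worth of case evidence), consistent with how
  in-trans evidence is aggregated for sequence variants; it is config, not
  a printed constant.
* **Phenotype specificity**: 0.15 once per variant when any reported
  individual has a phenotype highly specific to the disease, 0.30 when the
  evidence is particularly strong. The bonus stacks with functional
  evidence on the same observation; nothing in the framework forbids it,
  and the two address different evidence types.
* **X-linked case evidence** (`score_xl_cases()`): a fully explicit point
  table keyed by proband sex × de novo/inheritance status with the
  carrier-parent affected status folded into the inheritance key. The
  shipped values (e.g. male de novo confirmed 0.30) are package defaults
  chosen to mirror the recessive table's strength levels — they are *not*
  anchored to published numbers, which is why they live in config. The
  phenotype adjustment is added per case and the per-case contribution is
  bounded at 0.45.
* **De novo occurrence**: confirmed 0.45, assumed 0.30 (framework-level
  defaults, configurable). **Functional evidence**: supporting 0.15
  (expression or cellular assays), moderate 0.30, strong 0.45 (e.g. an
  animal model carrying the exact variant recapitulating the phenotype).
* **Complex SVs**: each canonical component is classified separately and
  the event takes the most deleterious component classification
  (B < LB < VUS < LP < P) — a deletion portion classified P with an
  uncertain duplication portion yields P overall.

A known tension documented rather than resolved: a de novo duplication
scoring 0.45 (de novo) + 0.45 (35–49 genes) totals 0.90, which is LP under
the default ranges, although such events are sometimes reported outright
pathogenic. The package asserts only the direction of the transition
(VUS at 28 genes → at least LP at 35); users who want P there can adjust
`ranges` or the de novo points.

## The synthetic generator

`generate_reference()` / `generate_cohort()` produce a fully seeded
mini-cosmos: ~150 non-overlapping genes on chr1 plus a handful on chrX with
5–10 exons of 130–170 bp and 2 kb introns; two gene-model sources, the
curated one missing a deterministic subset of genes so that multi-gene
events show discordant counts; Poisson-placed probes at 0.1/kb; a 100-entry
SV panel mixing common and rare alleles. The cohort (default 100 samples)
carries three causal implants with known expected classification —
a dominant de novo multi-gene deletion over the established
haploinsufficient gene (1.0 + 0.45 → P), optionally emitted as 2–4
fragments cut at intergenic boundaries the way read-depth callers fragment
large events; a recessive intragenic frameshifting multi-exon deletion with
an in-trans pathogenic second variant (0.90 + 0.30 → P); and an X-linked
hemizygous whole-gene deletion in a male (0.90 + 0.30 → P) — plus a common
benign deletion in 5% of samples at a panel locus. Background structure is
calibrated to the cleaned-callset shape seen in real cohorts: ~45
low-QS artifact calls per sample (QS mostly 21–49: above the QS-20 QC line,
below every analysis gate, and under 300 bp so they cannot link into rare
clusters), and rare incidental high-quality calls at ~2 per sample, each
occupying a distinct 3-exon window so the per-sample rare high-confidence
count has median 2.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: breakpoint uncertainty and exon-coverage
heterogeneity, batch structure in read depth, overlapping genes and
multi-transcript loci, mosaicism, and callers' systematic biases around
segmental duplications. The recovery tests demonstrate the pipeline's
bookkeeping is correct under the stated rules, not that the rules have any
particular sensitivity on real exomes.

## Numerical and degenerate-input choices

Frequency comparisons are exact (`<` for MOI limits, `≤ 0.01` for high
confidence) with no tolerance, as the constants are exact by construction.
Intervals with `start ≥ end` are rejected at the primitive level. Empty
event sets propagate as zero-row tibbles through every stage. Medians of an
empty score class are reported `NA`. Duplicate probe positions count once.
Single-component "complex" events classify as their single component. The
bisection and sweep resolutions used in the acceptance script (1% overlap
steps, integer QS) match the printed precision of the constants they
recover. Problem sizes in the tests — 1,000-case oracle comparisons,
200-call clustering closures, 100-sample cohorts — were chosen as the
smallest sizes at which the properties are non-trivially exercised.

## Limitations

Second variants enter as pre-classified labels; the package does not
classify sequence variants. Benign-direction evidence beyond the frequency
screens (e.g. full population-overlap scoring) is not implemented — the
engine's negative ranges exist but nothing currently emits negative points.
Breakpoint inference, liftover and sequence-level analysis are out of
scope. The fragmented-event deleteriousness-score fallback (max of
component scores) understates scores for truly large events; supplying a
recomputed span-level score is preferred.
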