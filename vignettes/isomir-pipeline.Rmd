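---
title: "From small-RNA reads to 5'isomiR biology: methods and design notes"
author: "isomirpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From small-RNA reads to 5'isomiR biology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirpair)
```

## The problem

A mature miRNA is produced by two endonucleolytic cuts, and neither cut is
perfectly precise. The resulting variants — isomiRs — differ at their 5'
and/or 3' ends from the canonical (miRBase-annotated) sequence. Because
target recognition is dominated by the seed (nucleotides 2–8), 3' variants
are functionally interchangeable with the canonical form, whereas a 5'
shift renumbers the whole sequence: a +1 5'isomiR's seed is the canonical
positions 3–9, and its reverse-complement 7-mer target site in 3'UTRs is
different. When a 5'isomiR is abundant, a cell effectively expresses two
miRNAs from one locus. This package implements the computational path for
finding such canonical/5'isomiR pairs in small-RNA-seq data and analyzing
their downstream associations; the hsa-miR-140-3p pair in breast cancer
cell lines and tumors is the running example.

## Offset notation and classification

Every read placed on a precursor is described by two integers relative to
a mature annotation on that precursor: `d5` = read start − annotated
start, `d3` = read end − annotated end, rendered `d5|d3` with explicit
signs (`0|0`, `+1|+2`, `0|-3`). Internally all coordinates are 0-based
half-open; the GFF3 convention (1-based inclusive) is converted exactly
once, at the file boundary. Sequences are stored as DNA (U→T on input) and
rendered as RNA only for display.

Classification into expression groups deliberately ignores the 3' end:
every read of length 18–24 nt is pooled by its 5' end into the key
(miRNA, `d5`), so `0|x` is the canonical group and `+1|x` the +1 5'isomiR
group. Two equivalent-looking conventions exist for bounding the 3' end:
a length window (18–24 nt) or enumerated offset windows
(`0|-3`…`0|+3`, `+1|-2`…`+1|+3`); they disagree at one edge (a 21-nt
mature at `+1|+4` has length 24 but lies outside the enumerated window).
The length rule is what is implemented; the window bounds are a
`quantify()` parameter.

## Quantification model

The pipeline per read is trim → map → assign → collapse:

* **Trimming** removes the longest read suffix that exactly matches a
  prefix of the 3' adapter (minimum overlap 6 nt). This replaces a
  generic trimmer with a deterministic, testable rule. Reads outside
  15–30 nt after trimming are flagged (`too_short`/`too_long`), never
  silently dropped.
* **Mapping** is exact (0 mismatches) against precursor sequences, sense
  strand only — small-RNA libraries are stranded and mature species derive
  from the hairpin. This is a deliberate simplification of
  genome-mapping-plus-annotation-intersection; it is equivalent for reads
  from annotated loci, but multi-locus families are resolved by fractional
  counting rather than genomic context (see Limitations). Reads that do
  not match exactly (sequencing errors, non-templated additions) stay
  unmapped, mirroring a 0-mismatch alignment policy.
* **Assignment** picks, among the mature annotations on the hit precursor,
  the one minimizing |`d5`| (ties: smaller |`d3`|, then the 5p arm), and
  rejects |`d5`| > 5 (`max_offset5`): a read that far from any annotated 5'
  end is more plausibly a degradation fragment than an isomiR.
* **Multi-mapping**: a read assignable to *n* distinct miRNA names gets
  weight 1/*n* per name; duplicate precursors carrying the same name count
  once. This conserves total counts across families.

**rpm normalization.** The denominator is the total weight of reads that
received an isoform key — not raw or mapped reads. The choice is the one
that makes the matrix self-contained (rpm sums to exactly 10⁶ per sample,
asserted to 10⁻⁶ relative tolerance in the tests); with a different
denominator convention all rpm values rescale by a per-sample constant and
the pair criteria below are affected only through the absolute 100-rpm
threshold.

## Pair detection

A miRNA with both a `0|x` and a `+1|x` key is a candidate pair; it passes
when the canonical mean rpm across samples is ≥ 100 and the ratio of means
(isomiR mean ÷ canonical mean) is ≥ 0.2 (1:5). "Ratio on average" could
also be read as the mean of per-sample ratios; the ratio of means is used
because it is robust to near-zero samples, and both readings agree on the
bundled eight-cell-line panel. Means weight all samples equally. Both
thresholds are parameters of `pair_criteria()`, and both passing and
failing candidates are returned so the filter is auditable.

## Seed scanning and enrichment

`seed_of()` returns positions 2–8; `target_site_of()` its reverse
complement; `scan_utr()` reports every (possibly overlapping) exact
occurrence. Matching is a plain 7-mer match: no 7mer-A1/8mer site classes,
no G:U wobble, no context scores. That is the minimal model under which a
one-nucleotide 5' shift cleanly partitions target sites, and it keeps the
enrichment test self-contained instead of depending on a versioned
external prediction database. `enrichment_test()` forms the 2×2 table
(downregulated vs rest of the gene universe) × (has ≥ 1 site vs none) and
applies a one-sided Fisher exact test for over-representation; tests
verify it against direct hypergeometric tail summation.

## Downregulation filter

A gene is called downregulated under a condition when, in **every** listed
cell line, treated/control expression is strictly below 0.65 and the
corrected p-value strictly below 0.05 — both bounds strict, so a gene
reduced by exactly 35 % or at exactly p = 0.05 is excluded.
Benjamini–Hochberg correction is the default (standard for microarray
DE), Bonferroni available. Correction is applied per cell line
and condition across genes. When a table carries replicates instead of
precomputed statistics, per-gene p comes from the same two-tailed unpaired
Student's t test used elsewhere. For two conditions the Venn partition
(specific-to-A, specific-to-B, shared) is reported. Microarray
preprocessing and normalization are out of scope: the filter consumes
ratio/p tables.

## Cohort statistics

* **Correlation** defaults to Pearson on the supplied expression scale
  (with an optional log2(x+1) flag), two-sided p from `cor.test`.
  Conventions differ across cohort studies, so both the coefficient type
  and the scale are exposed; Pearson-on-rpm is the default.
* **Group comparisons** are two-tailed unpaired Student's t tests
  (equal-variance, per the named method), reporting means, group sizes
  and direction.
* **Survival**: patients in the upper quartile of the chosen expression
  are "high", lower quartile "low", middle half excluded. Cut points use
  the median-unbiased quantile convention (type 8) with ties going to the
  lower group (low takes `x ≤ Q1`, high takes `x > Q3`); the convention
  is a parameter, since quartile definitions vary across software.
  Kaplan–Meier estimation and the 1-df log-rank test are delegated to the
  survival package; tests cross-check the statistic against a hand
  risk-table computation and the KM curve against the empirical survivor
  function in the uncensored case.

## The synthetic-data generator

The generator exists so that every downstream claim is tested against
known truth, through files, using only recorded truth tables:

* **Reference**: random precursors (default 80 nt) each embedding one
  mature sequence (20–23 nt) with ≥ 5 nt flanks; matures are pairwise
  non-substring and unique across the set, so read placement is
  unambiguous by construction.
* **Reads**: per-sample miRNA abundances are log-normal; offsets are drawn
  from a per-miRNA spectrum over `d5` ∈ [−2, +2] × `d3` ∈ [−3, +3]; every
  read is cut from its precursor, then the adapter is appended, then
  (optionally) bases are substituted at `error_rate` ≤ 0.05. Because the
  default spectrum can produce insert lengths outside the 18–24 nt
  collapse window, the truth table records intended counts both in total
  and within the window; recovery is asserted against the latter. With
  errors on, the assigned fraction is ≈ (1−e)^length — corrupted reads
  vanish under exact matching, which is asserted as a property.
* **DE tables**: planted hits get ratios in (0.35, 0.62) and raw p ≤
  5·10⁻⁵, which after BH across 500 genes stays strictly below 0.05 at any
  rank, so planted Venn counts are recovered exactly, by construction
  rather than by tuning.
* **Cohort**: expressions are bivariate log-normal. The underlying-normal
  correlation is solved in closed form from the log-normal moment relation
  ρ = log(1 + r·√((e^{σ₁²}−1)(e^{σ₂²}−1))) / (σ₁σ₂), so the output-scale
  Pearson correlation hits the target analytically, not by calibration
  loops. ER and metastasis status shift both isoforms on the log scale
  (defaults +0.1 for ER-negative, −0.08 for metastatic, ≈ 0.65 sd each);
  because such shared shifts add covariance on top of the solved value,
  correlation-recovery runs set them to zero. Survival is exponential with
  hazard scaled geometrically across expression-quartile groups
  (low 1, middle √HR, high HR; default HR 0.5, i.e. high expression
  survives better) from a baseline median of 2000 days; censoring times
  are exponential with rate λ·c/(1−c), making the expected censored
  fraction exactly c (default 0.6).

**What the generator does *not* emulate.** Real rpm distributions span
orders of magnitude; the cohort default σ_log = 0.15 is deliberately mild
so that normal-theory (Fisher-z) intervals for the output-scale Pearson r
are calibrated — at realistic dispersion (σ_log ≈ 0.8) the sampling sd of
r is ~1.7× the Fisher-z value and the nominal 95 % interval covers only
about two thirds of replicates. Passing recovery tests therefore
demonstrates correctness of the estimators and the analytic correlation
solve, not that Fisher-z intervals are trustworthy on heavy-tailed tumor
data (use Spearman or the log scale there). Likewise absent: quality-score
structure, non-templated additions, RNA editing, PCR duplicates, and any
dependence between expression and clinical covariates beyond the
configured shifts.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use: spectrum recovery at depth
20 000 (one miRNA, 70/30 split, 100 seeded replicates, 3-binomial-SE
bound); mapping oracle equivalence on 1000 reads × 50 precursors; UTR-scan
oracle equivalence on 1000 random 300–500 nt UTRs; BH oracle equivalence
up to length 10⁴; correlation recovery on 100 cohorts of n = 616; log-rank
null calibration on 1000 cohorts of n = 200; DE recovery on 500 genes with
planted (30, 10, 4). Determinism: a single integer seed drives every
generator; sub-generators derive fixed offsets from it, so outputs are
byte-identical across runs and independent of call order. Floating-point
assertions use 10⁻⁶ relative tolerance for the rpm conservation identity
and exact equality where arithmetic is exact (counts, Venn partitions).

## Known limitations

* Exact-match precursor mapping cannot distinguish family members whose
  mature sequences coincide; they are fractionally split, and 5'isomiR
  calls for such families should be treated with caution.
* The enrichment analogue replaces curated target predictions with exact
  7-mer presence; it measures seed-site over-representation, not validated
  targeting.
* The downregulation filter assumes expression ratios and p-values are
  already on a comparable scale across cell lines (preprocessing is out of
  scope).
* Negative-offset (5'-extended) isomiR seeds require precursor context and
  are not derivable from the canonical mature sequence alone
  (`shifted_seed` refuses them).
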