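---
title: "Detecting genetically redundant accessions in clonal collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetically redundant accessions in clonal collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgtools)
library(dplyr)
```

## The problem

Genebanks conserving vegetatively propagated crops (cassava, potato, yam,
banana) accumulate *genetic redundancy*: the same clone catalogued under
several accession numbers, through renaming by farmers, record-keeping
errors, or mix-ups across decades of in-vitro multiplication. Because
conservation cost scales with accession count, curators want to partition
the collection into *multilocus genotypes* (MLGs): groups of accessions
whose pairwise genetic distances are small enough to be explained by
genotyping error rather than by genuine genetic difference.

The whole question therefore reduces to a threshold: below which distance
do two samples count as "the same genotype"? `mlgtools` implements the
empirical answer used in modern genebank screens: genotype technical and
biological replicates of a subset of accessions, measure the distance
distribution among replicate pairs — distances that are *known* to be
pure error — and place the threshold just above the largest of them.

## Data model

Two marker systems are supported side by side, as produced by
genotyping-by-sequencing platforms:

* **Codominant SNP dosages** (0/1/2, alternate-allele count). Pairwise
  dissimilarity is the identity-by-state (IBS) distance: at each locus
  where both samples are called, shared alleles are `2 - |ga - gb|`; the
  distance is `1 -` (shared alleles)/(2 × called loci). The measure is
  invariant to which allele is labelled "reference", so no allele
  resolution is needed.
* **Dominant presence/absence markers** ("silico" markers, restriction
  fragment detection). Dissimilarity is the Jaccard distance
  `(b + c) / (a + b + c)` over pairwise-complete loci, where `a` counts
  joint presences and `b`, `c` the one-sided presences. Joint absences
  are excluded: absence of a fragment in both samples carries no
  evidence of shared ancestry for a dominant marker.

Missing data are handled pairwise-complete in both metrics. A pair with
no informative loci at all gets a flagged sentinel (1 for IBS, 0 for
Jaccard) rather than an exception, so one failed sample cannot abort a
collection-wide run; flagged pairs are excluded from merging and
reported.

## Quality control

Distances among replicates only calibrate error if marker- and
sample-level artefacts are controlled first.

**Marker cascades** apply ordered, inclusive filters; a marker removed at
one stage is not reconsidered. Defaults (SNP): `maf >= 0.001`,
`call_rate >= 0.8`, `avg_marker_count >= 12`, `cv_marker_count <= 0.6`,
`rep_avg >= 0.98`, mapped to the reference genome. Defaults (silico):
`call_rate >= 0.95`, `one_ratio >= 0.05`, `avg_read_depth >= 12`,
`cv_read_depth <= 0.7`, `reproducibility >= 0.98`. The final survivor
set equals the intersection of the single-filter survivor sets; the
ordering only attributes *which* stage removed a marker. Matrix-derived
statistics (maf, call rates, one-ratio) are recomputed whenever the
sample set changes; depth and reproducibility statistics come from the
genotyping provider and are fixed inputs.

**Sample rules** are open keep-intervals; a sample is excluded when it
falls outside at least one. Defaults: total tag count > 1,500,000,
unique tag count > 230,000, SNP call rate > 0.73, observed
heterozygosity Ho strictly between 0.05 and 0.16, silico one-ratio
> 0.2. High Ho is the signature of cross-contaminated DNA (a mixture of
two diploids reads as heterozygous wherever the two genotypes differ in
allele content); low call rates and tag counts betray degraded or weak
libraries. No default rule is placed on the per-sample silico call
rate: the published account of this screen is internally inconsistent
about that rule's direction (a `> 0.996` keep-rule against a cohort
mean of 0.97 would discard nearly everything), so the rule must be
configured explicitly if wanted. The library QC category
(good/downshifted/weak) is reported but never excludes on its own.

## Threshold calibration

Replicates come in three classes, ordered by how much of the error
process they capture: **DNA-Reps** (same DNA assayed twice; pure
genotyping error), **Extract-Reps** (separate extractions of one
individual; adds extraction artefacts), **Ind-Reps** (distinct
individuals of one accession; adds somatic divergence and tracking
error). `calibrate_threshold()` reports each class's distance
distribution and proposes the smallest multiple of a grid (default
0.005) *strictly greater* than the pooled maximum replicate distance.
The grid round-up rule is this package's reading of how the reference
thresholds (0.06 from a maximum of 0.0576; 0.015 from 0.0127) were
chosen; the published account never states a formula, so the rule and
grid are configurable and the underlying statistics are always printed
for curator override.

`collapse_mlg()` then merges samples agglomeratively while the linkage
distance is strictly below the threshold ("falling below": equality
does not merge). Linkage is `farthest` by default (a cluster is an MLG
only if *every* cross pair is below threshold — the conservative choice,
and the one consistent with validating clusters as rectangles on a
complete-linkage dendrogram); `nearest` (equivalent to connected
components of the sub-threshold graph) and `average` are available
because the original analysis never names its collapsing linkage. Ties
are broken towards the lexicographically smallest sample id and MLG ids
are the smallest member id, so results are exactly reproducible. The
study design this mirrors runs calibration on the replicate cohort and
the final collapse over one representative sample per accession
(`collection_samples()`).

## The synthetic collection

`simulate_collection()` generates the full study structure with ground
truth, so every stage is testable without any external download:

* founder genotypes drawn per marker from Hardy–Weinberg proportions at
  allele frequencies uniform on [0.01, 0.09] — a low-frequency spectrum
  chosen so the simulated cohort's mean Ho (~0.09) matches what cassava
  GBS cohorts actually show, and sits inside the default Ho
  keep-interval;
* a configurable number of clone accessions per founder (default 2–4
  over 40 founders) — the true redundancy structure;
* a replicate cohort (default 8 accessions, one per founder) each with
  the 7-sample set used in calibration experiments: 2 DNA-Reps,
  2 Extract-Reps, 3 Ind-Reps, with class-specific per-allele miscall
  rates (defaults 0.002 / 0.004 / 0.008; plain collection samples use
  the individual-level rate, since each is one individual);
* per-allele miscall as an allele-copy flip (dosage ±1 within bounds;
  bit-flip for dominant markers), random per-cell missingness (default
  0.01);
* a fraction of technically poor markers (default 15%) with shallow
  depth statistics, low reproducibility and a 15× error multiplier —
  this is what makes the marker cascade measurably shrink replicate
  distances, as a real cascade does;
* injected low-quality samples with three failure modes: *low_depth*
  (tag counts below the keep thresholds, extra missingness),
  *contaminated* (cellwise mixed-DNA calls: wherever the two source
  founders jointly carry both alleles the call is heterozygous with
  detection probability `4f(1-f)` for mixing weight `f`, inflating Ho),
  and *predigested* (downshifted library, heavy missingness, low call
  rate);
* descriptors (passport fields plus five morphological
  characterization variables) generated per founder and copied to its
  accessions, with configurable record-error and missing-data rates to
  emulate historical characterization conflicts.

Everything is reproducible byte-for-byte from the seed.

What the generator does **not** emulate: linkage disequilibrium between
markers, population structure among founders, allele-frequency
differences between regions, read-level depth variation within a
sample, and error correlated across replicate classes. Tests passing on
this generator therefore demonstrate that the *procedure* is correct
and calibrated under its own assumptions — not that any particular real
collection satisfies those assumptions.

## Reporting

* `summarize_partition()` turns a partition (or a bare size
  distribution, so published summary tables can be re-processed) into
  the curator's numbers: MLG count, redundant accessions, percent
  distinct/redundant (half-up, two decimals).
* `threshold_sweep()` tabulates MLG counts over a threshold range;
  counts are non-increasing in the threshold.
* `compare_partitions()` crosses the SNP and silico partitions:
  per-accession single/multi classes, the two mismatch directions, and
  both-multi accessions whose exact MLG sizes differ (exact sizes, not
  size categories — configurable).
* `region_summary()` bins accessions by region of origin into the C1 /
  C2 / C3–C5 / C6+ MLG size categories, with percent distinctness
  `100 × C1/total` rounded half-up to one decimal and redundancy as its
  exact complement, so the two always sum to 100.0. The denominator is
  the category sum by default; an externally supplied total is accepted
  with a warning when it disagrees.
* `descriptor_concordance()` scores, per redundancy case and variable,
  the number of distinct recorded classes among members with data; one
  class = a "one" (the descriptor corroborates the genetic call). Two
  counting rules exist for cases where only one member has data:
  per-variable totals exclude them by default, per-case totals count
  them; both are switchable, because published worked examples apply
  the exclusion inconsistently between the two margins.
* `hierarchical_cluster()` (complete or ward.D2 via `stats::hclust`)
  and `to_newick()` produce visualization-grade trees; branch lengths
  are parent-minus-child merge heights, leaves at height zero, children
  ordered by smallest leaf label, parseable by standard Newick readers.

## Numerical choices and edge cases

* Thresholds in filter cascades are inclusive exactly as printed;
  boundary markers are retained. Sample keep-intervals are open
  (a value equal to a bound is flagged).
* Percentages use half-up rounding (two decimals for collection
  summaries, one for regional tables), matching how such tables are
  printed; `round()`'s banker's rounding is deliberately not used.
* The calibration grid round-up treats a pooled maximum within 1e-9 of
  a grid multiple as sitting on it, and still proposes the next step,
  preserving the strict inequality under floating-point noise.
* Degenerate distance pairs (no shared called loci; no shared
  presences) never merge and are carried through partitions as flagged
  metadata.
* A marker or sample with zero calls gets its undefined statistics
  reported as 0/NA with a flag; the call-rate rules remove it anyway.

## Known limitations

* The threshold proposal presumes replicate pairs experience the same
  error process as collection samples; error modes unique to the
  collection (e.g. historical mislabelling) are invisible to it and
  surface only as over-threshold pairs inside MLGs.
* At very low error rates the margin between the proposal and the
  noise tail is governed by the grid step; with per-allele error 0.001
  and 2,000 markers the 0.005 grid line sits only ~4.5 standard
  deviations above the mean clone-pair distance, so a small percentage
  of simulated collections show a single clone pair just above the
  proposal. The recovery guarantee is therefore stated at the 95%
  level, not higher.
* Farthest-linkage MLGs are order-sensitive in principle; determinism
  here comes from the lexicographic tie-break, not from the linkage.
* The agglomerative implementation is dense O(n³); it is comfortable
  to a few thousand samples but not engineered for collections orders
  of magnitude larger.

## Problem sizes used in the test suite

The suite validates against brute-force oracles on small random
instances (up to 15 samples, 200 instances for the collapse oracles),
and runs the full pipeline on synthetic collections of 40 founders ×
2–4 clones with 2,000 SNP and 2,000 dominant markers — about 165
samples — across 40 seeds for genotype recovery and 20 seeds for the
replicate-distance structure, sizes chosen to exercise every code path
at seconds-per-seed cost.
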