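---
title: "Autozygosity mapping and homozygous variant prioritization with autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and homozygous variant prioritization with autozyg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The study design this package implements

Mating between relatives leaves a recognizable genomic signature in the
offspring: long **runs of homozygosity** (ROHs), stretches several megabases
long in which both haplotypes descend from the same recent ancestor
(*autozygosity*). Inside such a region every variant is homozygous, so rare
recessive deleterious alleles — ordinarily hidden in carriers — are expressed.
A classic prioritization strategy for recessive variation in complex disease
therefore proceeds in three steps:

1. **Homozygosity mapping.** Call ROHs from SNP-array genotypes and select
   the subjects whose burden of *long* ROHs (> 4 Mb) marks probable recent
   inbreeding.
2. **Variant filtration.** Within those subjects' ROHs, filter exome variant
   calls down to homozygous, low-frequency, protein-affecting variants
   (**LFF**), the predicted-damaging subset (**LFF-D**), and finally the
   novel-or-extremely-rare, never-seen-homozygous **best candidates**.
3. **Gene-set enrichment.** Ask whether the genes hit by LFF/LFF-D variants
   overlap disease gene sets more than chance, using permutation nulls that
   respect the gene content of the ROH regions themselves.

`autozyg` implements all three stages as composable functions plus a seeded
end-to-end pipeline, and ships a synthetic-data generator that implants
autozygous segments and annotated variants with full ground truth, so every
stage can be validated and calibrated without access to any cohort data.

## ROH detection

`detect_rohs()` uses the scanning-window algorithm family standard for
array data (the approach popularized by PLINK's `--homozyg`):

* a window of `window_snps` (default 50) consecutive markers is *homozygous*
  if it contains at most `max_het_in_run` heterozygous (default 1) and
  `max_missing_in_run` missing (default 5) calls;
* a marker joins a run if more than `window_threshold` (default 5 %) of the
  windows covering it are homozygous;
* maximal flagged stretches are split wherever consecutive markers are more
  than `max_gap` (default 100 kb) apart, and kept if they span at least
  `min_length` (default 1 Mb), contain at least `min_snps` (default 50)
  markers, and average no more than `min_density` (default 50 kb) per marker.

The het/missing allowance is deliberately *per window*, not per run: a
multi-megabase autozygous segment genotyped with a realistic per-marker error
rate contains several heterozygous miscalls, and a run-level limit of one
would shatter exactly the long runs the design needs to find.

**End refinement.** Window voting alone has a known edge artifact: with a
1-het window allowance, a run can bleed across a single flanking heterozygote
into the adjacent homozygous background, biasing boundaries outward by many
markers. `detect_rohs()` therefore trims each run to the outermost
homozygous call that has no heterozygote within its terminal half-window.
On error-free simulations this reduces the boundary error to the
irreducible component — the run of background markers that happen to be
homozygous beyond the true segment end, about `(1-h)/h` markers for
background heterozygosity `h` — which is what makes per-segment Jaccard
recovery above 0.99 attainable at the default marker density. The same rule
is stated declaratively and re-implemented naively in the test suite's
brute-force oracle, and the detector is required to match it exactly on
a thousand random fixtures.

Run-level coordinates are 0-based half-open, from the first marker of the
run to one past its last marker. All internal interval arithmetic in the
package uses this single convention; VCF and PLINK MAP positions (1-based)
are converted at the I/O boundary. This removes a whole class of off-by-one
ambiguities in ROH–variant containment, which the tests probe with
variants placed on the exact boundary markers.

**Selecting ROH-individuals.** `select_roh_individuals()` applies the
two-step rule: keep subjects with at least one ROH longer than
`long_threshold` (default 4 Mb), then keep those whose long-ROH count
strictly exceeds the third quartile (type-7, linear interpolation) of the
survivors. The strict inequality handles threshold ties symmetrically: if
all survivors share one count, no one is "in the upper quartile". On a
27-subject cohort whose long-ROH counts have median 2 with seven subjects
above 4, the rule selects exactly those seven.

## The filtration cascade

`tier_variants()` evaluates conjunctive predicates per variant, so the
cascade is order-independent and every non-LFF variant carries exactly one
machine-readable exclusion reason:

* **LFF**: homozygous-alt, inside a ROH of at least `roh_min` (1 Mb),
  functional consequence (missense, stop gain/loss, start loss, splice site,
  frameshift, in-frame indel), every *reported* database allele frequency
  below `maf_max` (0.05), not blacklisted, not in a low-copy CNV.
* **LFF-brain**: LFF and brain expression `FPKM > 1` (strict).
* **LFF-D**: LFF and a damaging consensus of at least `damaging_min = 2` of
  the three predictors, with the tools' published call conventions —
  SIFT < 0.05, PolyPhen-2 HDIV ≥ 0.957, MutationTaster ≥ 0.5. The 2-of-3
  rule (rather than all-three) is forced by the reference best-candidate
  calls, which include a variant with a tolerated SIFT call alongside
  damaging PolyPhen-2 and MutationTaster calls.
* **Best candidate**: LFF-D, in a ROH *strictly* longer than `best_roh_min`
  (3 Mb), novel (absent from all three databases) or with maximum reported
  frequency below `rare_af_max` (1e-4), and never reported homozygous.
  Database fields distinguish *absent* (`NA`) from zero: novelty means
  absent everywhere, while an absent homozygote count is treated as zero
  (databases differ in what they report). phyloP conservation is carried
  and reported but never used as a filter, since no cutoff is established
  for it in this design.

Two pre-filters mirror the practical QC of amplicon-based exomes:
`apply_blacklist_and_cnv()` drops known false-positive indels by exact
(chrom, pos, ref, alt) match, and flags variants falling inside a
same-sample CNV with copy number below 2, where an apparently homozygous
genotype may actually be hemizygous. `compute_titv()` provides the standard
transition/transversion sanity check (≈ 2.5 expected for human exomes).

The cohort summary (`summarize_tiers()`) counts per-subject variants and
genes at each tier and adds an `All` row with **distinct** semantics: a
variant or gene seen in two subjects counts once. This is the aggregation
that must reproduce the reference per-cohort totals when fed the per-patient
counts.

## Enrichment testing

`permutation_overlap_test()` draws `n_perm` same-size gene lists uniformly
without replacement from a background universe and reports the add-one
empirical p-value `(b + 1)/(n_perm + 1)` (never zero; resolution 1e-4 at the
default 9,999 permutations). When the number of distinct draws is small
(≤ 10,000) it switches to exhaustive enumeration and the p-value is exact.
The background is a modelling choice exposed to the caller: testing LFF
genes against the genes contained in the cohort's ROH regions (rather than
all genes) makes the null density-aware — an enrichment that survives this
background is not an artifact of disease genes being concentrated inside
ROHs. The pipeline uses the ROH-gene background by default.

`interval_enrichment_test()` is the interval-based analogue (INRICH-style):
the statistic is the number of ROH intervals overlapping at least one
target-set gene, and the null relocates each interval uniformly within its
chromosome, preserving length and resampling until the relocated interval
holds a total gene count within ±20 % of the original, so local gene density
is matched. The full two-stage bootstrap correction of the original INRICH
scheme is out of scope; multiple sets are corrected with Benjamini–Hochberg,
as is `hypergeometric_ora()`, the closed-form over-representation test
(upper-tail hypergeometric), which also flags sets with fewer than two query
overlaps as conventionally unreportable.

Gene identifiers are matched as uppercased symbols with no alias resolution;
alias maps are database-versioned and out of scope.

## What the synthetic generator emulates

`sim_config()` defaults describe a deliberately scaled-down cohort chosen to
be computable in seconds while preserving the structure of the study design
above:

* **Genome and markers**: three 50 Mb chromosomes with one marker per kb and
  Beta(3, 3) allele frequencies. Array markers are ascertained toward common
  SNPs; Beta(3, 3) gives mean heterozygosity ≈ 0.43, so a false extension of
  a detected run beyond a true segment boundary dies out after one or two
  background markers (geometric with rate ≈ 0.43). The real array's
  post-QC marker density is not documented in this design's sources; density
  here is an explicit free parameter, not a claim.
* **Cohort structure**: 30 subjects of which 7/30 are "inbred", each
  receiving a Poisson(5) number of autozygous segments with Exponential
  (mean 8 Mb) lengths — the magnitude, not a pedigree model, of
  recent-inbreeding autozygosity. Segments are truncated at chromosome ends
  (recorded in the truth) and merged when they collide.
* **Genotypes**: Hardy–Weinberg draws per marker outside segments; inside a
  segment one allele is drawn by its frequency and both haplotypes carry it,
  then perturbed by a genotype error (hom → het, default 0.002) and missing
  rate (default 0.01). Background heterozygosity therefore has the HWE
  closed form `mean(2p(1-p))`, which the tests verify to within three
  binomial standard deviations.
* **Exome variants**: planted only at gene positions for candidate tiers,
  at 10/Mb inside and outside segments, with transitions drawn at odds
  Ti/Tv = 2.5. Each in-ROH variant samples an intended tier
  (non-candidate / LFF / LFF-D / best, default weights 0.92/0.05/0.02/0.01,
  matching the order of magnitude of the reference per-patient tier counts);
  annotations are then drawn to *earn* that tier, and the recorded truth
  tier is re-evaluated from the drawn annotation by an independent
  rule evaluator — so, e.g., a drawn database homozygote count above zero
  demotes a would-be best candidate in the truth itself. Non-candidates get
  one deterministic blocking feature (synonymous consequence, common
  frequency, or heterozygous call) so that tier recovery can be required to
  be *exact*, not probabilistic. Damaging variants draw each predictor
  damaging with probability 0.9, forced to at least 2 of 3, which reproduces
  the observed "tolerated SIFT among best candidates" pattern.
* **Planting margins**: candidate variants are only planted in segments
  comfortably clear of the tier gates (LFF tiers ≥ 1.2 Mb, best > 3.5 Mb,
  10 kb off segment edges). Detected run boundaries are uncertain by about
  one inter-marker spacing; without the margins a truth label could flip at
  the 1 Mb / 3 Mb gates for segments sitting exactly on them, turning an
  estimator-precision question into a spurious tier-recovery failure.

What the generator does **not** emulate: linkage disequilibrium (background
runs arise only from drift around the HWE draws), allele-frequency spectra
of real exomes, site-specific error processes, pedigree-consistent segment
placement, and real gene annotation. Passing recovery tests therefore
demonstrate the correctness of the algorithms under the stated model, not
performance on any particular array or capture platform.

## Numerical and statistical choices

* **Quantiles and medians**: the upper-quartile rule uses R's type-7
  (linear interpolation) quantile; per-subject median ROH length uses the
  interpolated median (mean of the middle two for even counts).
* **Empirical p-values** use the add-one correction in sampled mode and
  exact enumeration when feasible; permutation counts default to 9,999.
* **Calibration test design**: uniformity of the null p-value is checked by
  KS against U(0, 1) over 1,000 replicate tests at 999 permutations. The
  overlap statistic is discrete, so the comparison is only meaningful when
  its null atoms are far below the KS resolution (`1.63/sqrt(1000)` ≈ 0.05);
  the calibration experiment uses a 5,000-gene universe, a half-universe
  target and 1,000-gene queries, giving a null standard deviation ≈ 14 and a
  largest atom ≈ 0.03. Power is regression-tested by injecting a 17 %
  enrichment into 107-gene queries against a 10 %-of-background set — the
  reference effect size — and requiring rejection at α = 0.05 in well over
  half of 200 seeded replicates.
* **Degenerate inputs**: zero-marker chromosomes warn and drop; empty
  cohorts yield empty run tables; a Ti/Tv with no transversions is reported
  absent with a warning; selection with no step-1 survivor returns an empty
  set with a warning rather than an error.
* **Determinism**: every stochastic stage takes a seed; the pipeline derives
  per-stage sub-seeds from one master seed, so stages rerun standalone
  reproduce their in-pipeline results, and identical config + seed produce
  byte-identical artifacts (the run manifest is sufficient to reproduce a
  simulated run exactly, which the tests verify).

## Problem sizes used in the validation suite

The test and acceptance workloads use 20–30 subjects on two or three 40–50 Mb
chromosomes (80,000–150,000 markers), 1,000 random ≤ 200-marker fixtures for
the detector-vs-oracle sweep, 1,000 replicates for null calibration, 500 for
FDR calibration and 200 for power — sizes chosen so the full suite completes
in a few minutes on one core while every estimate retains a comfortable
Monte-Carlo margin.

## Known limitations

* The ROH caller is a window/voting scanner; it is not a likelihood or
  HMM-based autozygosity model, and its published commercial counterparts
  have unpublished parameter defaults, so cross-software run counts are not
  expected to be bit-identical on real data.
* FROH-style inbreeding coefficients are exposed only as the convenience
  ratio `total ROH length / genome length`.
* The interval test matches relocated intervals on gene count only; gene
  length-matched gene sampling is not implemented.
* In-cohort allele-frequency filtering (confirmatory genotyping of a local
  population) is out of scope; a local-frequency column, if supplied in the
  annotation table, is treated identically to the database frequencies.
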