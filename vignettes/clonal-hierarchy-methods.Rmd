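---
title: "Models and methods behind clonehier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonehier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(clonehier)
```

`clonehier` reconstructs per-patient clonal architecture from targeted
sequencing read counts in myeloid cohorts and analyzes how the position of
a mutation in the clonal hierarchy — ancestral/dominant versus secondary —
relates to phenotype, therapy response and survival.  This vignette
explains the models, the tunable parameters, the synthetic-data generator
used for validation, and the design choices made where the design was
genuinely open.

## From read counts to tumor cell fractions

The raw observation for a mutation is `alt_reads` out of `depth` reads,
giving the observed VAF.  A heterozygous mutation present in a fraction
φ of cells on copy-neutral background has expected VAF φ/2; copy-number
changes distort this.  `estimate_tcf()` applies branch formulas keyed by
the overlapping region class:

| branch | condition | TCF |
|---|---|---|
| neutral | no CNA overlap | 2·VAF |
| deletion | TCN < 2 | TCN·VAF |
| UPD, mutation first | VAF > 0.5(1 − AsCN) | 2·VAF − 1 + AsCN |
| UPD, UPD first | VAF ≤ 0.5(1 − AsCN) | 2·VAF |
| gain | TCN fixed at 3 | 3·VAF |

Notes on the edges, which the formulas leave open:

* **Clamping.** The gain branch exceeds 1 whenever VAF > 1/3, and the
  late-UPD branch can stray outside [0, 1] as well.  Values are clamped
  to [0, 1] with a `clamped` flag rather than rejected — downstream
  clustering needs bounded prevalences, and the flag preserves the audit
  trail.
* **The UPD threshold.** The two UPD branches do not agree in the limit
  at VAF = 0.5(1 − AsCN) (they tend to 0 and 1 − AsCN respectively), so
  the boundary is a genuine discontinuity in the published mapping.  We
  assign the boundary to the early branch, which is continuous with the
  neutral case, and flag such calls `boundary` for audit rather than
  silently smoothing the formula.
* **Missing copy-number data** defaults every mutation to the neutral
  branch.

`vaf_expected()` is the exact algebraic inverse per branch, used as the
emission mean of the clustering model; the round-trip identity
`estimate_tcf(vaf_expected(φ)) = φ` holds exactly wherever no clamping
occurs and is property-tested.

## The Dirichlet-process beta-binomial mixture

Per patient, mutations are clustered over cellular prevalence with a
Dirichlet-process mixture:

* assignments follow a Chinese-restaurant process with concentration 1;
* each cluster has a prevalence φ with Beta(1, 1) base measure;
* `alt_reads ~ BetaBinomial(depth, ξ, s)` where ξ is the copy-number-aware
  expected VAF of φ (clipped to [0.001, 0.999], the sequencing error
  floor) and the precision s has a Gamma(shape 1.0, rate 0.001) prior.

Defaults are 10,000 iterations with burn-in 1,000 (`dp_config()`); the
test suite and examples run shorter chains (typically 2,000/200 or
300/50) because the per-patient problems are small — a dozen mutations at
depth several hundred — and recovery is already stable there; an
invariant check in the suite verifies that shortening the chain does not
change recovered labels materially.

The sampler uses collapsed assignment updates with three auxiliary
components, and random-walk Metropolis updates for φ (logit scale,
proposal SD 0.5) and s (log scale, proposal SD 0.3).  Initialization puts
every mutation in its own cluster at its TCF estimate; s starts at its
prior mean (1,000).  Mutations are put into canonical
(chrom, pos, ref, alt) order before seeding, making results independent
of input row order, and each patient's chain is seeded from the run seed
plus a hash of the patient identifier, making results independent of
patient order.

**Consensus.** Point estimates come from the posterior co-assignment
(similarity) matrix: average-linkage hierarchical clustering on
1 − similarity, cut at the number of clusters maximizing the posterior
expected adjusted Rand criterion (PEAR) against the similarity matrix.
This replaces an unparameterized dynamic-tree-cut step with a standard,
reproducible criterion that needs no tuning constants.  Clusters whose
posterior mean prevalence falls below the error floor are merged into
their nearest neighbor (a numerical guard for phantom near-zero
clusters).

**Labels.** The cluster with the highest posterior mean prevalence is the
dominant clone; its mutations are dominant, all others secondary.  We
read "largest clone" as highest cellular prevalence (the ancestral clone
under nesting), which matches the observation that dominant mutations
carry the top adjusted VAFs; `largest_by = "members"` switches to the
most-populous reading.  Prevalence ties are broken by member count, then
by the smallest canonical mutation identifier, and the tie is recorded
(a potential "co-dominant" situation; only two levels are emitted).
Mutations excluded from clustering (indels, repetitive regions) are
labeled post hoc by nearest prevalence so that association analyses see
every mutation; an option drops them instead.

## Association statistics

All contingency analytics run through `fisher_2x2()`: the two-sided exact
p-value is the sum of hypergeometric probabilities of tables no more
probable than the observed one (the standard point-probability
convention, with the usual 1 + 1e-7 relative slack), and the reported
odds ratio is the sample cross-product (a·d)/(b·c) with an explicit
infinity convention.  The cross-product, not the conditional MLE, is what
published cohort tables report for degenerate pairs; the conditional MLE
is available for cross-checking, and the two can round differently at one
decimal.

`pair_tables()` tests every gene dominant in more than 1% of patients
against every gene secondary in more than 1% (strict thresholds), with
one Benjamini–Hochberg family per run; `lesion_correlation()` uses the
asymmetric significance convention (q < 0.01 for coexistence, q < 0.25
for exclusivity).  Phenotype odds ratios for pairs compare patients
carrying both the dominant and the secondary event against patients
carrying neither, dropping partial carriers — the three-step procedure
used for pair-effect analyses.  Confidence intervals are Woolf logit
intervals with Haldane 0.5 correction applied to the interval only, never
to the point estimate.  For the morphology dichotomy, sAML patients enter
through their antecedent class (MDS or MDS/MPN) when recorded.

## CH classification

Dominant genes determine the class: any CH-related dominant gene
(DNMT3A, TET2, ASXL1, JAK2) makes the patient CH-related; otherwise any
dominant gene outside both sets makes the patient CH-unrelated; patients
whose dominant genes all sit in the overlapping set (TP53, SF3B1, SRSF2,
GNB1, CBL), or who have no mutations, are Overlapping.  The precedence
for mixed dominant sets is a package decision (the published rule does
not cover them): "any CH-related gene wins" matches the observation that
nearly all CH-related patients carry at least one such dominant
mutation, and mixed overlapping/unrelated sets are flagged in the output
for audit.  Secondary mutations never influence the class.

## Digital copy number

The exon-depth pipeline standardizes each sample's summed exon depths to
unit total, selects the 12 best-Pearson-correlated normals as a
reference panel, forms per-exon copy ratios against the panel mean on
exons whose cohort mean raw depth exceeds 500 (strict), median-centers
each profile, segments it, and calls lesions at 4 SD.

* **Median centering.** Standardizing to a fixed total shifts all of a
  lesion-bearing sample's neutral exons (mass lost to a deletion is
  redistributed), so each profile is re-centered at its median before
  segmentation; `center = "none"` disables.
* **Segmentation** is circular binary segmentation: the maximal
  two-segment statistic over circular split pairs, tested against a
  within-segment permutation null (1,000 permutations, α = 0.01,
  minimum width 2 exons — all configurable).  The profile is treated as
  circularly closed: the first significant split separates an arc from
  its *wrapped complement, which stays one segment*, so a focal lesion
  does not fragment the flanking neutral sequence into independently
  wobbling pieces; both arcs are then refined recursively.
* **Calling.** Per exon, the mean E and SD of the segmented ratio are
  computed across all cohort samples (the "for all samples" reading; a
  flag switches to a panel-based reference and a 1% trimmed SD is
  available), and a value is a loss/gain only if strictly beyond
  E ± 4 SD.  Losses translate to deletion (TCN 1, AsCN 0) and gains to
  TCN 3; copy-neutral LOH is invisible to depth and must come from SEG
  input.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a large MDS cohort so that
every downstream stage can be validated against ground truth:

* **Clone counts** default to 52.5% single-clone patients with the
  remaining mass decaying over 2–7 clones (mode 2 among multiclonal
  patients), matching the reported fraction of multiclonal samples and
  the 1–7 range.
* **Prevalences** are nested along a linear chain: the founder draws
  φ₁ ~ Beta(8, 2) (mean 0.8, so dominant neutral VAFs center near 0.40)
  and each child multiplies its parent by Beta(5, 3).  An option allows
  one branching event to exercise tie-breaking.
* **Genes** come from the packaged 36-gene panel with synthetic marginal
  frequencies and dominant shares chosen to emulate the reported
  marginals (TET2 27%, SF3B1 23%, ASXL1 19%, …; SF3B1/U2AF1/TP53
  dominant-leaning, ASXL1/CBL/KRAS secondary-leaning).  The panel is a
  configuration, not a hard filter.
* **Read counts**: depth ~ negative binomial (mean 796, dispersion 3),
  truncated at the depth-20 filter; alt reads ~ Binomial(depth, ξ) at the
  copy-number-aware expected VAF.  Mutations are heterozygous except
  inside simulated UPD, where the mutation-first/UPD-first genotype is
  drawn at random.
* **Lesions**: del(5q) 16%, −7/del(7q) 10%, a chromosome-8 gain 5%, and
  UPD at 4q/11q/9p — regions chosen so that panel genes (NPM1, EZH2,
  RAD21, TET2, CBL, JAK2) can overlap them.
* **Phenotypes** are logistic with configurable dominant/secondary pair
  effects (defaults: dominant TET2 + secondary SRSF2 toward MDS/MPN,
  dominant RUNX1 + secondary ASXL1 toward high risk, dominant SF3B1 +
  secondary DNMT3A or JAK2 toward low risk); baseline rates 12.5%
  MDS/MPN and 42% high-risk.
* **Survival** is exponential with baseline median 27 months and
  multiplicative group hazards (defaults: dominant TP53 2.9, secondary
  TP53 1.5, high-risk 1.8, CH-unrelated 1.45), with independent uniform
  censoring on [0, 120] months.  **HMA response** is Bernoulli at
  baseline 30% with per-gene log-odds (TET2 +log 2.4, ASXL1 +log 0.45)
  among the ~10% treated.

What the generator does *not* emulate: positional hotspots, trinucleotide
context, sequencing batch effects, subclonal copy number, correlated
censoring, or real gene–gene interaction structure beyond the configured
pair effects.  Passing recovery tests on this generator therefore shows
the estimators are correct under the stated model, not that the
biological conclusions transfer to any particular real cohort.

## Numerical choices and degenerate inputs

* Exact p-values are clamped to [0, 1] against floating-point overshoot
  of the hypergeometric sum.
* An all-zero 2×2 table, an empty cohort, an all-zero depth sample, and
  p-values outside [0, 1] raise classed validation errors.
* A single-mutation patient yields one cluster; a patient whose mutations
  are all excluded from clustering gets a single pseudo-clone at the mean
  TCF.
* The KM median is the earliest time with S(t) ≤ 0.5 (undefined when
  never reached); Cox fits with complete event separation are flagged
  non-estimable rather than reported; ties use the Efron approximation.
* VAF stratification puts the boundary value (e.g. exactly 0.4) in the
  low stratum, and uses a patient's maximum VAF when several mutations
  hit the stratifying gene.

## Problem sizes used in the validation suite

Recovery checks run at deliberately modest but sufficient sizes: 20
seeded two-clone patients (prevalences 0.8/0.3, five mutations per clone,
depths 500–1,200, 2,000-iteration chains) for label and prevalence
recovery; 50 replicates of 2,000 patients for the null calibration of
pair discovery; 20 replicates of a 120-exon, 40-normal cohort with an
8-exon heterozygous deletion (0.5× depth, CV 5%) for the copy-number
pipeline; 20 replicates of 400 subjects for Cox recovery at a generating
hazard ratio of 1.93.  These sizes give stable pass/fail behaviour across
seeds while keeping the default check runnable on a laptop.

## Known limitations

* Clonal hierarchy is reduced to two levels; no phylogenetic tree beyond
  dominant/secondary is reconstructed, and co-dominance is only flagged,
  not modeled.
* The emission uses total copy number through the branch mapping rather
  than a full genotype-prior marginalization; for two-level reduction the
  information content is the same, but subclonal copy number is out of
  scope.
* Bulk single-timepoint data cannot determine whether two secondary
  mutations share a subclone; labels are per-mutation only.
* UPD cannot be detected from depth; it must be supplied via SEG input.
* The multivariate survival modeling that a clinical analysis would add
  on top of the univariate comparisons is out of scope.
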