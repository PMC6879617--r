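# clonehier

Clonal hierarchy reconstruction and dominant/secondary mutation analytics
for myeloid cohorts.

## The problem

Myelodysplastic syndromes (MDS) arise by stepwise acquisition of somatic
mutations: an ancestral ("dominant") hit founds the malignant clone and
later ("secondary") hits create nested subclones.  Bulk targeted
sequencing sees only read counts per mutation, so the clonal position of
each mutation has to be inferred.  `clonehier` implements that inference
and the downstream analytics for cohorts of MDS / MDS-MPN patients:

1. **Copy-number-aware VAF adjustment.** The observed variant allele
   frequency (VAF) is mapped to the tumor cell fraction (TCF) carrying
   the mutation, using the overlapping copy-number state:
   TCF = TCN·VAF for deletions (and gains, with TCN fixed at 3);
   TCF = 2·VAF − 1 + AsCN for mutations inside a UPD region with
   VAF > 0.5(1 − AsCN) (UPD after the mutation); TCF = 2·VAF otherwise.
2. **Dirichlet-process beta-binomial clustering.** Per patient, mutations
   are clustered over cellular prevalence φ with a DP mixture
   (concentration 1, Beta(1,1) base measure) and a beta-binomial read
   count emission (precision ~ Gamma(1.0, 0.001), error floor 0.001),
   sampled by MCMC (default 10,000 iterations, burn-in 1,000).  Consensus
   clusters come from the posterior similarity matrix via average-linkage
   clustering with a PEAR-maximizing cut.  Mutations of the
   highest-prevalence clone are labeled *dominant*, all others
   *secondary*.
3. **Association statistics.** Exhaustive dominant→secondary pair tables
   (Fisher exact tests with cross-product odds ratios and
   Benjamini–Hochberg correction), lesion–lesion co-occurrence /
   mutual-exclusivity maps, phenotype odds ratios (MDS vs MDS/MPN,
   low vs high IPSS-R risk), and hypomethylating-agent (HMA) response
   associations.
4. **CH classification.** Patients are classed by their dominant genes as
   CH-related (DNMT3A/TET2/ASXL1/JAK2), CH-unrelated, or overlapping
   (TP53/SF3B1/SRSF2/GNB1/CBL), linking MDS to antecedent clonal
   hematopoiesis.
5. **Survival.** Kaplan–Meier curves, log-rank tests and univariate Cox
   hazard ratios for rank groups, VAF strata and CH classes.
6. **Digital copy number.** A panel-of-normals exon-depth pipeline
   (standardization, correlation-selected panel of 12, copy ratios on
   exons with mean depth > 500, circular binary segmentation, 4-SD
   gain/loss calls).
7. **Synthetic cohorts.** A seeded generator producing read counts,
   copy-number lesions, phenotypes, survival and therapy response with
   full ground truth, so every stage is testable without patient data.

## Worked example

```r
library(clonehier)

cfg <- run_config(
  simulate = sim_config(n_patients = 40, seed = 3),
  dp = dp_config(iterations = 300, burn_in = 50),
  seed = 3
)
res <- run_all(cfg)

cohort_summary(res$architecture)$clone_histogram
#> # A tibble: 4 × 3
#>   n_clones n_patients fraction
#>      <int>      <int>    <dbl>
#> 1        1         27    0.675
#> 2        2          7    0.175
#> 3        3          4    0.1
#> 4        4          2    0.05

head(res$pairs[order(res$pairs$p), c("dominant", "secondary",
  "co_occurrence", "odds_ratio", "p", "q")], 3)
#> # A tibble: 3 × 6
#>   dominant secondary co_occurrence odds_ratio     p     q
#>   <chr>    <chr>             <int>      <dbl> <dbl> <dbl>
#> 1 CALR     MPL                   1        Inf 0.025     1
#> 2 ETV6     ETV6                  1        Inf 0.025     1
#> 3 ETV6     NF1                   1        Inf 0.025     1
```

The clone-count histogram shows how many clones the sampler resolved per
patient (most patients are single-clone, as in real MDS cohorts).  Each
pair row is a 2×2 table over patients: `co_occurrence` counts patients
whose dominant gene is X *and* secondary gene is Y; the odds ratio is the
cross-product estimate (`Inf` when no discordant patients exist), `p` the
two-sided Fisher p-value and `q` its BH adjustment — at this toy cohort
size nothing survives correction, as expected.

Single-patient fits follow broom conventions:

```r
adj <- adjust_vaf(filter_variants(res$cohort$mutations),
                  res$cohort$cn_segments)
fit <- fit_patient(dplyr::filter(adj, patient_id == "P0002"),
                   dp_config(iterations = 2000, burn_in = 200))
glance(fit)
#> # A tibble: 1 × 4
#>   n_mutations n_clones precision_mean n_samples
#>         <int>    <int>          <dbl>     <int>
#> 1           2        1          1142.      1800
tidy(fit)
#> # A tibble: 2 × 5
#>   mut_id              gene  cluster phi_mean phi_sd
#>   <chr>               <chr>   <int>    <dbl>  <dbl>
#> 1 P0002:4:106000583:2 TET2        1    0.911 0.0405
#> 2 P0002:X:15800530:1  ZRSR2       1    0.907 0.0405
```

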