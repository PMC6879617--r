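Package: clonehier
Title: Clonal Hierarchy Reconstruction and Dominant/Secondary Mutation
    Analytics for Myeloid Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-patient clonal architecture from targeted
    sequencing read counts in myelodysplastic syndrome cohorts.  Adjusts
    observed variant allele frequencies for overlapping copy-number states
    (deletion, gain, uniparental disomy) into tumor cell fractions, clusters
    mutations per patient with a Dirichlet-process beta-binomial mixture
    sampler, reduces the hierarchy to dominant versus secondary mutation
    ranks, and provides exhaustive dominant-to-secondary pair association
    statistics (Fisher tests with Benjamini-Hochberg correction), phenotype
    and hypomethylating-therapy odds ratios, clonal-hematopoiesis-related
    classification, digital copy-number calling from exon depth matrices,
    and survival comparisons.  Includes a seeded synthetic-cohort generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
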