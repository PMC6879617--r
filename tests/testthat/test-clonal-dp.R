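dp_test_config <- function(...) {
  dp_config(iterations = 1200, burn_in = 200, ...)
}

test_that("a single mutation always occupies one cluster", {
  mut <- adjust_vaf(tibble::tibble(
    patient_id = "P1", chrom = "1", pos = 1, ref = "A", alt = "T",
    gene = "TET2", alt_reads = 40, depth = 100, vaf_obs = 0.4
  ))
  fit <- fit_patient(mut, dp_test_config(seed = 1))
  expect_true(all(fit$z == 1L))
  cons <- consensus_clusters(fit)
  expect_equal(nrow(cons$clusters), 1)
  expect_equal(cons$clusters$phi_mean, 0.8, tolerance = 0.1)
})

test_that("the sampler is deterministic and invariant to input row order", {
  mut <- adjust_vaf(make_two_clone_patient(seed = 5))
  fit1 <- fit_patient(mut, dp_test_config(seed = 2))
  fit2 <- fit_patient(mut, dp_test_config(seed = 2))
  expect_identical(fit1$z, fit2$z)
  expect_identical(fit1$phi, fit2$phi)
  expect_identical(fit1$s, fit2$s)

  perm <- mut[sample(nrow(mut)), ]
  fit3 <- fit_patient(perm, dp_test_config(seed = 2))
  expect_identical(fit1$z, fit3$z)
  expect_identical(fit1$phi, fit3$phi)
})

test_that("two well-separated clones are recovered with correct labels", {
  mut <- adjust_vaf(make_two_clone_patient(phis = c(0.8, 0.2),
    per_clone = 8, depth_range = c(800, 1200), seed = 7))
  fit <- fit_patient(mut, dp_test_config(seed = 3))
  cons <- consensus_clusters(fit)
  expect_equal(nrow(cons$clusters), 2)
  expect_equal(sort(cons$clusters$phi_mean), c(0.2, 0.8), tolerance = 0.06)

  lab <- label_dominant(cons, fit)
  merged <- dplyr::inner_join(
    dplyr::select(lab, mut_id, label),
    dplyr::select(mut, mut_id, true_label), by = "mut_id")
  expect_equal(merged$label, merged$true_label)

  # posterior mean phi lies near the members' TCF hull
  for (k in cons$clusters$cluster) {
    members <- which(cons$assignment == k)
    hull <- range(fit$mutations$tcf[members])
    sd3 <- 3 * max(cons$clusters$phi_sd[cons$clusters$cluster == k], 1e-3)
    expect_gte(cons$clusters$phi_mean[cons$clusters$cluster == k],
      hull[1] - sd3)
    expect_lte(cons$clusters$phi_mean[cons$clusters$cluster == k],
      hull[2] + sd3)
  }
})

test_that("consensus reproduces exact block structure from an agreed trace", {
  # fabricated trace: all samples agree on two blocks
  z <- matrix(rep(c(1L, 1L, 1L, 2L, 2L), each = 50), nrow = 50)
  phi <- matrix(rep(c(0.8, 0.8, 0.8, 0.3, 0.3), each = 50), nrow = 50)
  fit <- structure(list(
    z = z, phi = phi, s = rep(1000, 50),
    mutations = tibble::tibble(mut_id = paste0("m", 1:5), gene = "G",
      chrom = "1", pos = 1:5, tcf = c(0.8, 0.8, 0.8, 0.3, 0.3)),
    config = dp_config(iterations = 100, burn_in = 10)
  ), class = "dp_fit")
  cons <- consensus_clusters(fit)
  expect_equal(cons$assignment, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(cons$clusters$phi_mean, c(0.8, 0.3))
})

test_that("dominant labeling breaks prevalence ties by member count", {
  z <- matrix(rep(c(1L, 1L, 1L, 2L), each = 40), nrow = 40)
  phi <- matrix(0.4, nrow = 40, ncol = 4)
  fit <- structure(list(
    z = z, phi = phi, s = rep(1000, 40),
    mutations = tibble::tibble(mut_id = paste0("m", 1:4), gene = "G",
      chrom = "1", pos = 1:4, tcf = rep(0.4, 4)),
    config = dp_config(iterations = 100, burn_in = 10)
  ), class = "dp_fit")
  cons <- consensus_clusters(fit)
  lab <- label_dominant(cons, fit)
  expect_equal(lab$label, c("dominant", "dominant", "dominant", "secondary"))
  expect_true(attr(lab, "phi_tied"))
})

test_that("excluded mutations are labeled by nearest prevalence", {
  mut <- adjust_vaf(make_two_clone_patient(per_clone = 6, seed = 11))
  excl <- adjust_vaf(tibble::tibble(
    patient_id = "P1", mut_id = c("P1:x1", "P1:x2"), gene = c("XA", "XB"),
    chrom = "2", pos = 1:2, ref = "A", alt = "T",
    alt_reads = c(390, 80), depth = 1000, vaf_obs = c(0.39, 0.08),
    bidirectional = TRUE, excluded = TRUE
  ))
  fit <- fit_patient(mut, dp_test_config(seed = 4))
  cons <- consensus_clusters(fit)
  lab <- label_dominant(cons, fit, excluded = excl)
  got <- lab[match(c("P1:x1", "P1:x2"), lab$mut_id), ]
  expect_equal(got$label, c("dominant", "secondary"))
  expect_true(all(got$excluded))
})

test_that("infer_architecture labels a small cohort and summarizes it", {
  sim <- simulate_cohort(sim_config(n_patients = 25, seed = 17))
  adjusted <- adjust_vaf(filter_variants(sim$mutations), sim$cn_segments)
  arch <- infer_architecture(adjusted, dp_test_config(seed = 5))
  expect_s3_class(arch, "clonal_architecture")
  expect_equal(nrow(arch), nrow(adjusted))
  expect_true(all(arch$label %in% c("dominant", "secondary")))
  # every patient has at least one dominant mutation
  per <- arch |> dplyr::group_by(patient_id) |>
    dplyr::summarise(has_dom = any(label == "dominant"))
  expect_true(all(per$has_dom))

  summ <- cohort_summary(arch)
  expect_equal(sum(summ$clone_histogram$n_patients),
    dplyr::n_distinct(arch$patient_id))
  expect_equal(sum(summ$clone_histogram$fraction), 1)
})

test_that("dominant aVAFs exceed secondary aVAFs in a constructed cohort", {
  # construct labels directly: dominant phi ~ 2x secondary phi
  set.seed(23)
  n <- 500
  lab <- sample(c("dominant", "secondary"), n, TRUE)
  arch <- tibble::tibble(
    patient_id = sprintf("P%03d", sample(100, n, TRUE)),
    gene = "G", cluster = ifelse(lab == "dominant", 1L, 2L), label = lab,
    tcf = ifelse(lab == "dominant", rbeta(n, 16, 4), rbeta(n, 8, 12))
  )
  summ <- cohort_summary(arch)
  expect_gt(summ$vaf_comparison$median_dominant,
    summ$vaf_comparison$median_secondary)
  expect_lt(summ$vaf_comparison$p_ranksum, 0.05)

  # all-dominant cohort: secondary fraction 0 for every gene
  summ2 <- cohort_summary(dplyr::mutate(arch, label = "dominant", cluster = 1L))
  expect_true(all(summ2$gene_ranks$dominant_fraction == 1))
  expect_null(summ2$vaf_comparison)
})

test_that("tidy and glance expose the fit in broom form", {
  mut <- adjust_vaf(make_two_clone_patient(per_clone = 5, seed = 29))
  fit <- fit_patient(mut, dp_test_config(seed = 6))
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(mut))
  expect_true(all(c("mut_id", "cluster", "phi_mean", "phi_sd") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_mutations, nrow(mut))
  expect_gte(gl$n_clones, 1)
})
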