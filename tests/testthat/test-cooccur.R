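test_that("fisher_2x2 matches hand enumeration and the infinity convention", {
  r1 <- fisher_2x2(3, 0, 0, 3)
  expect_equal(r1$p, 2 / 20)
  expect_equal(r1$odds_ratio, Inf)

  r2 <- fisher_2x2(2, 0, 0, 2)
  expect_equal(r2$p, 1 / 3)

  expect_equal(fisher_2x2(0, 2, 3, 1)$odds_ratio, 0)
  expect_true(is.nan(fisher_2x2(0, 2, 0, 2)$odds_ratio))
  expect_error(fisher_2x2(0, 0, 0, 0), class = "clonehier_validation_error")
})

test_that("fisher_2x2 p agrees with stats::fisher.test over random tables", {
  set.seed(77)
  for (i in 1:200) {
    tot <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, tot, runif(4)))
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    p_our <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(p_our, p_ref, tolerance = 1e-10)
  }
})

test_that("cross-product and conditional-MLE estimators differ as expected", {
  # printed cohort rows that round identically only under one estimator
  cp <- fisher_2x2(19, 90, 17, 1683)$odds_ratio
  cm <- fisher_2x2(19, 90, 17, 1683, estimator = "cmle")$odds_ratio
  expect_equal(round(cp, 1), 20.9)
  expect_equal(round(cm, 1), 20.8)
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "clonehier_validation_error")

  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in p-rank
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm]) # permutation-invariant
  expect_equal(q, stats::p.adjust(p, "BH")) # independent reference
})

test_that("pair tables count the four patient classes and flag degenerate pairs", {
  # 20 patients where X dominant and Y secondary always co-occur,
  # 180 with neither
  arch <- dplyr::bind_rows(
    tibble::tibble(patient_id = sprintf("A%03d", 1:20), gene = "X",
      label = "dominant"),
    tibble::tibble(patient_id = sprintf("A%03d", 1:20), gene = "Y",
      label = "secondary"),
    tibble::tibble(patient_id = sprintf("B%03d", 1:180), gene = "Z",
      label = "dominant")
  )
  res <- pair_tables(arch, n_patients = 200)
  xy <- res[res$dominant == "X" & res$secondary == "Y", ]
  expect_equal(unname(unlist(xy[, c("co_occurrence", "dominant_only",
    "secondary_only", "intact")])), c(20, 0, 0, 180))
  expect_equal(xy$odds_ratio, Inf)
  expect_equal(xy$direction, "co_occurrence")
  expect_true(all(res$co_occurrence + res$dominant_only +
      res$secondary_only + res$intact == 200))
  expect_error(pair_tables(arch[0, ]), class = "clonehier_validation_error")
})

test_that("frequency thresholds for tested genes are strict", {
  # gene at exactly 1% of patients must not be tested
  arch <- dplyr::bind_rows(
    tibble::tibble(patient_id = "P001", gene = "RARE", label = "dominant"),
    tibble::tibble(patient_id = sprintf("P%03d", 1:30), gene = "COMMON",
      label = "dominant"),
    tibble::tibble(patient_id = sprintf("P%03d", 5:40), gene = "SEC",
      label = "secondary")
  )
  res <- pair_tables(arch, n_patients = 100)
  expect_false("RARE" %in% res$dominant)
  expect_true("COMMON" %in% res$dominant)
})

test_that("the packaged pair table reproduces printed odds ratios", {
  tab <- pair_counts_reference()
  expect_equal(nrow(tab), 37)
  expect_true(all(tab$co_occurrence + tab$dominant_only +
      tab$secondary_only + tab$intact == 1809))
  ft <- fisher_2x2(tab$co_occurrence, tab$dominant_only,
    tab$secondary_only, tab$intact)
  printed <- suppressWarnings(as.numeric(tab$or_printed))
  comparable <- is.finite(printed)
  # cross-product rounds to the printed OR within one rounding step for
  # every finite row (two estimator conventions differ by <= 0.1)
  expect_true(all(abs(round(ft$odds_ratio[comparable], 1) -
      printed[comparable]) <= 0.1 + 1e-9))
  # direction always consistent with the printed CO/ME flag
  expect_equal(ft$odds_ratio > 1, tab$direction == "CO")
})

test_that("lesion correlation flags coexistence and exclusivity asymmetrically", {
  # perfectly co-occurring lesions
  les <- dplyr::bind_rows(
    tibble::tibble(patient_id = sprintf("P%03d", 1:40), lesion = "L1"),
    tibble::tibble(patient_id = sprintf("P%03d", 1:40), lesion = "L2")
  )
  res <- lesion_correlation(les, n_patients = 200)
  expect_true(res$significant[1])
  expect_equal(res$direction[1], "co_occurrence")

  # disjoint lesions at 30% each among 500 patients
  les2 <- dplyr::bind_rows(
    tibble::tibble(patient_id = sprintf("P%03d", 1:150), lesion = "A"),
    tibble::tibble(patient_id = sprintf("P%03d", 151:300), lesion = "B")
  )
  res2 <- lesion_correlation(les2, n_patients = 500)
  expect_equal(res2$direction, "mutual_exclusivity")
  expect_true(res2$significant)

  # a lesion at 2% (not > 2%) is not tested
  les3 <- dplyr::bind_rows(les2,
    tibble::tibble(patient_id = sprintf("P%03d", 1:10), lesion = "RARE"))
  res3 <- lesion_correlation(les3, n_patients = 500)
  expect_false("RARE" %in% c(res3$lesion_a, res3$lesion_b))
})

test_that("phenotype odds ratios are null under independence and recover effects", {
  set.seed(31)
  coh <- make_labeled_cohort(n = 600, seed = 31)
  res <- phenotype_or(coh$architecture, coh$clinical,
    grouping = "single_lesion", phenotype = "mpn")
  expect_true(all(res$q > 0.1)) # balanced synthetic: no signal
  expect_true(all(is.finite(res$ci_low) | res$ci_non_estimable))

  # injected pair effect: patients with both dominant X / secondary Y are
  # much more often MDS/MPN
  n <- 800
  pid <- sprintf("Q%04d", 1:n)
  carrier <- seq_len(n) <= 200
  arch <- dplyr::bind_rows(
    tibble::tibble(patient_id = pid[carrier], gene = "X", label = "dominant"),
    tibble::tibble(patient_id = pid[carrier], gene = "Y", label = "secondary"),
    tibble::tibble(patient_id = pid[!carrier], gene = "Z", label = "dominant")
  )
  base_lo <- stats::qlogis(0.12)
  pr <- stats::plogis(base_lo + 1.5 * carrier)
  clin <- tibble::tibble(
    patient_id = pid,
    diagnosis = ifelse(stats::runif(n) < pr, "MDS_MPN", "MDS"),
    ipssr_score = 2, os_months = 10, os_event = FALSE,
    hma_treated = FALSE, hma_response = NA_character_
  ) |> clonehier:::derive_risk_group()
  res2 <- phenotype_or(arch, clin, grouping = "pair_both_vs_neither",
    phenotype = "mpn",
    genes = tibble::tibble(dominant = "X", secondary = "Y"))
  expect_true(res2$ci_low < exp(1.5) && exp(1.5) < res2$ci_high)

  # degenerate pair: zero "both" patients
  res3 <- phenotype_or(arch, clin, grouping = "pair_both_vs_neither",
    phenotype = "mpn",
    genes = tibble::tibble(dominant = "X", secondary = "NOPE"))
  expect_true(res3$a + res3$b == 0)
  expect_true(res3$ci_non_estimable)
})

test_that("sAML patients enter the morphology dichotomy via antecedent class", {
  clin <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    diagnosis = c("sAML", "sAML", "MDS"),
    antecedent = c("MDS_MPN", "MDS", NA),
    ipssr_score = 2, os_months = 5, os_event = TRUE,
    hma_treated = FALSE, hma_response = NA_character_
  ) |> clonehier:::derive_risk_group()
  ind <- clonehier:::phenotype_indicator(clin, "mpn")
  expect_equal(ind$positive, c(TRUE, FALSE, FALSE))
})

test_that("HMA association reproduces the reference responder odds ratios", {
  ft1 <- fisher_2x2(23, 20, 44, 92)
  expect_equal(round(ft1$odds_ratio, 1), 2.4)
  ft2 <- fisher_2x2(19, 12, 48, 100)
  expect_equal(round(ft2$odds_ratio, 1), 3.3)

  # end-to-end on a constructed treated cohort with a known carrier split
  pid <- sprintf("P%03d", 1:179)
  clin <- tibble::tibble(
    patient_id = pid, diagnosis = "MDS", ipssr_score = 2,
    os_months = 10, os_event = FALSE,
    hma_treated = TRUE,
    hma_response = c(rep("CR", 23), rep("none", 20), # TET2 carriers
      rep("PR", 44), rep("none", 92)) # wild-type
  ) |> clonehier:::derive_risk_group()
  arch <- tibble::tibble(patient_id = pid[1:43], gene = "TET2",
    label = "dominant")
  res <- hma_association(arch, clin, genes = "TET2")
  resp <- res[res$outcome == "responder", ]
  expect_equal(unname(unlist(resp[, c("a", "b", "c", "d")])),
    c(23, 20, 44, 92))
  expect_equal(round(resp$odds_ratio, 1), 2.4)

  expect_error(
    hma_association(arch, dplyr::mutate(clin, hma_treated = FALSE)),
    class = "clonehier_validation_error"
  )
})
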