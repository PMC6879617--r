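test_that("the product-limit estimator matches hand computation", {
  km <- km_estimate(tibble::tibble(os_months = c(1, 2, 3),
    os_event = c(TRUE, TRUE, TRUE)))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2) # earliest time with S <= 0.5

  # no events: flat at 1, median undefined
  km2 <- km_estimate(tibble::tibble(os_months = c(5, 8),
    os_event = c(FALSE, FALSE)))
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))

  # single subject with an event
  km3 <- km_estimate(tibble::tibble(os_months = 5, os_event = TRUE))
  expect_equal(km3$curve$surv, 0)
  expect_equal(km3$median, 5)

  expect_error(km_estimate(tibble::tibble(os_months = -1, os_event = TRUE)),
    class = "clonehier_validation_error")
})

test_that("without censoring the KM estimate equals the empirical survival", {
  set.seed(51)
  for (i in 1:5) {
    tt <- round(stats::rexp(60, 0.1), 2)
    km <- km_estimate(tibble::tibble(os_months = tt, os_event = TRUE))
    emp <- vapply(km$curve$time, function(u) mean(tt > u), numeric(1))
    expect_equal(km$curve$surv, emp, tolerance = 1e-12)
  }
})

test_that("the log-rank test behaves at the null and under strong effects", {
  dat <- tibble::tibble(
    os_months = rep(c(3, 5, 8, 12), 2), os_event = TRUE,
    group = rep(c("a", "b"), each = 4)
  )
  res <- logrank(dat, "group")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # two-group statistic equals the squared standardized O-E score
  set.seed(52)
  dat2 <- tibble::tibble(
    os_months = stats::rexp(120, rep(c(0.05, 0.15), each = 60)),
    os_event = TRUE, group = rep(c("a", "b"), each = 60)
  )
  res2 <- logrank(dat2, "group")
  g <- attr(res2, "groups")
  sd_ <- survival::survdiff(
    survival::Surv(dat2$os_months, rep(1, nrow(dat2))) ~ dat2$group)
  z2 <- (g$observed[1] - g$expected[1])^2 / sd_$var[1, 1]
  expect_equal(res2$chisq, z2, tolerance = 1e-9)

  # power at hazard ratio 3, n = 200 per group
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    d <- tibble::tibble(
      os_months = stats::rexp(400, rep(c(0.05, 0.15), each = 200)),
      os_event = TRUE, group = rep(c("a", "b"), each = 200))
    logrank(d, "group")$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(logrank(dat[dat$group == "a", ], "group"),
    class = "clonehier_validation_error")
})

test_that("log-rank type-I error is near nominal under label permutation", {
  set.seed(53)
  tt <- stats::rexp(80, 0.08)
  pvals <- vapply(1:300, function(i) {
    g <- sample(rep(c("a", "b"), each = 40))
    logrank(tibble::tibble(os_months = tt, os_event = TRUE, group = g),
      "group")$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("Cox hazard ratios are near 1 for identical groups and flag degeneracy", {
  set.seed(54)
  tt <- stats::rexp(200, 0.1)
  res <- cox_hr(rep(c(TRUE, FALSE), 100), tt, rep(TRUE, 200))
  expect_equal(res$hr, 1, tolerance = 0.5)

  res2 <- cox_hr(c(TRUE, FALSE, TRUE), c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(res2$non_estimable)
  expect_error(cox_hr(rep(TRUE, 5), stats::rexp(5), rep(TRUE, 5)),
    class = "clonehier_validation_error")
})

test_that("Cox estimation recovers a generating hazard ratio", {
  hrs <- vapply(1:8, function(s) {
    set.seed(s)
    ind <- rep(c(FALSE, TRUE), each = 200)
    tt <- stats::rexp(400, 0.05 * ifelse(ind, 1.93, 1))
    cens <- stats::runif(400, 0, 60)
    cox_hr(ind, pmin(tt, cens), tt <= cens)$hr
  }, numeric(1))
  expect_gt(mean(hrs), 1.7)
  expect_lt(mean(hrs), 2.2)
})

test_that("survival by rank builds the four groups and the VAF strata", {
  set.seed(55)
  n <- 450
  pid <- sprintf("P%04d", 1:n)
  # groups: both (1-50), dominant only (51-150), secondary only (151-200),
  # neither (201-450); ordered hazards both > dom-only > neither
  arch <- dplyr::bind_rows(
    tibble::tibble(patient_id = pid[1:150], gene = "TP53",
      label = "dominant", vaf_obs = stats::runif(150, 0.25, 0.6)),
    tibble::tibble(patient_id = pid[c(1:50, 151:200)], gene = "TP53",
      label = "secondary", vaf_obs = stats::runif(100, 0.05, 0.2))
  )
  haz <- log(2) / 44 * dplyr::case_when(
    pid %in% pid[1:50] ~ 4.3,
    pid %in% pid[51:150] ~ 2.9,
    pid %in% pid[151:200] ~ 1.8,
    TRUE ~ 1
  )
  t_ev <- stats::rexp(n, haz)
  cens <- stats::runif(n, 0, 100)
  clin <- tibble::tibble(
    patient_id = pid, diagnosis = "MDS", ipssr_score = 2,
    os_months = pmin(t_ev, cens), os_event = t_ev <= cens,
    hma_treated = FALSE, hma_response = NA_character_
  ) |> clonehier:::derive_risk_group()

  res <- survival_by_rank(arch, clin, gene = "TP53", vaf_cut = 0.4)
  expect_setequal(unique(res$groups$group),
    c("both", "dominant_only", "secondary_only", "neither"))
  expect_lt(res$logrank$p, 0.01)
  meds <- vapply(res$km[c("both", "dominant_only", "neither")],
    function(k) k$median, numeric(1))
  expect_true(meds["both"] < meds["neither"])
  expect_true(meds["dominant_only"] < meds["neither"])
  hr_both <- res$cox_vs_wildtype$hr[res$cox_vs_wildtype$group == "both"]
  expect_gt(hr_both, 1.5)

  # VAF boundary: exactly 0.4 goes to the low stratum
  strata <- res$vaf_strata$membership
  expect_true(all(strata$stratum[strata$max_vaf <= 0.4] == "low_vaf"))
  arch2 <- dplyr::mutate(arch, vaf_obs = 0.4)
  res2 <- survival_by_rank(arch2, clin, gene = "TP53", vaf_cut = 0.4)
  expect_true(all(res2$vaf_strata$membership$stratum == "low_vaf"))

  # absent gene: warning and empty result
  expect_warning(out <- survival_by_rank(arch, clin, gene = "NOPE"))
  expect_equal(nrow(out$groups), 0)
})

test_that("a neutral-region VAF cut equals the equivalent TCF cut", {
  set.seed(56)
  vaf <- stats::runif(40, 0.05, 0.6)
  tcf <- estimate_tcf(vaf, "neutral")$tcf
  expect_equal(vaf > 0.4, tcf > 0.8)
})
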