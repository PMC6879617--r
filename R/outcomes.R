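#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator of overall survival with Greenwood standard
#' errors.  The median is the earliest time at which the estimated
#' survival drops to 0.5 or below (`NA` when never reached).  Without
#' censoring the estimate equals the empirical survival function.
#'
#' @param data A data frame with time and event columns.
#' @param time,event Column names (default `os_months`, `os_event`).
#' @return A list of class `km_fit`: `curve` (tibble `time, n_risk,
#'   n_event, surv, std_err`) and `median`.
#' @export
km_estimate <- function(data, time = "os_months", event = "os_event") {
  check_columns(data, c(time, event), what = "survival data")
  tt <- data[[time]]
  ev <- as.integer(data[[event]])
  if (length(tt) < 1) stop_validation("at least one subject required")
  if (any(tt < 0, na.rm = TRUE)) stop_validation("negative survival time")
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  curve <- tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, std_err = sf$std.err * sf$surv  # Greenwood SE of S(t)
  )
  med <- curve$time[curve$surv <= 0.5]
  structure(list(
    curve = curve,
    median = if (length(med) > 0) min(med) else NA_real_
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d event times, median %s\n",
    nrow(x$curve),
    if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected chi-square test comparing survival
#' curves across `k` groups (degrees of freedom `k - 1`).
#'
#' @param data Data frame with time, event and group columns.
#' @param group Grouping column name.
#' @param time,event Column names.
#' @return A tibble `chisq, df, p` plus per-group observed/expected counts
#'   in the `groups` attribute.
#' @export
logrank <- function(data, group, time = "os_months", event = "os_event") {
  check_columns(data, c(time, event, group), what = "survival data")
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop_validation("logrank needs at least two groups")
  if (any(table(g) == 0)) stop_validation("a group has zero subjects")
  sd_ <- survival::survdiff(
    survival::Surv(data[[time]], as.integer(data[[event]])) ~ g
  )
  df <- nlevels(g) - 1
  out <- tibble(
    chisq = sd_$chisq, df = df,
    p = pchisq(sd_$chisq, df, lower.tail = FALSE)
  )
  attr(out, "groups") <- tibble(
    group = levels(g), n = as.vector(table(g)),
    observed = sd_$obs, expected = sd_$exp
  )
  out
}

#' Univariate Cox hazard ratio for a binary group indicator
#'
#' Partial-likelihood fit (Efron tie handling) of a single binary
#' covariate; returns the hazard ratio with Wald confidence interval and
#' p-value.  Monotone-likelihood fits (complete separation of events) are
#' flagged non-estimable rather than reported.
#'
#' @param indicator Logical/0-1 vector (group membership).
#' @param times Survival times.
#' @param events Event indicators.
#' @param level Confidence level.
#' @return A tibble `hr, ci_low, ci_high, p, non_estimable`.
#' @export
cox_hr <- function(indicator, times, events, level = 0.95) {
  ind <- as.integer(as.logical(indicator))
  ev <- as.integer(events)
  if (length(unique(ind)) < 2) {
    stop_validation("both indicator levels must be present")
  }
  if (sum(ev) == 0 || any(tapply(ev, ind, sum) == 0)) {
    return(tibble(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p = NA_real_, non_estimable = TRUE))
  }
  fit <- survival::coxph(survival::Surv(times, ev) ~ ind,
    ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  non_est <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se)
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    hr = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    non_estimable = non_est
  )
}

#' Survival by mutation rank for one gene
#'
#' Builds the four patient groups for a gene — carriers of both dominant
#' and secondary mutations, dominant only, secondary only, and
#' non-carriers — runs the Kaplan-Meier estimator per group, an overall
#' log-rank test across the non-empty groups, pairwise Cox hazard ratios
#' against the non-carrier group, and (optionally) a VAF stratification of
#' carriers at `vaf_cut` (strictly above vs at-or-below; when a patient
#' has several mutations in the gene the maximum VAF is used).
#'
#' @param architecture Labeled architecture tibble (needs `vaf_obs` for
#'   the VAF strata; [infer_architecture()] keeps it).
#' @param clinical Clinical tibble.
#' @param gene Gene symbol.
#' @param vaf_cut Optional VAF threshold (e.g. 0.4); `NULL` disables.
#' @return A list with `groups` (tibble `patient_id, group`), `km` (named
#'   list of [km_estimate()] fits), `logrank`, `cox_vs_wildtype` (tibble
#'   per non-reference group), and `vaf_strata` (KM + log-rank + Cox for
#'   the VAF cut, or `NULL`).  Returns an empty result with a warning if
#'   the gene is absent.
#' @export
survival_by_rank <- function(architecture, clinical, gene, vaf_cut = NULL) {
  check_columns(architecture, c("patient_id", "gene", "label"),
    what = "architecture")
  gmut <- filter(architecture, .data$gene == !!gene)
  if (nrow(gmut) == 0) {
    warn(sprintf("gene %s not present in cohort", gene))
    return(list(groups = tibble(patient_id = character(), group = character()),
      km = list(), logrank = NULL, cox_vs_wildtype = NULL,
      vaf_strata = NULL))
  }
  dom_ids <- unique(gmut$patient_id[gmut$label == "dominant"])
  sec_ids <- unique(gmut$patient_id[gmut$label == "secondary"])
  groups <- tibble(patient_id = clinical$patient_id) |>
    mutate(group = dplyr::case_when(
      .data$patient_id %in% intersect(dom_ids, sec_ids) ~ "both",
      .data$patient_id %in% dom_ids ~ "dominant_only",
      .data$patient_id %in% sec_ids ~ "secondary_only",
      TRUE ~ "neither"
    ))
  dat <- inner_join(groups, clinical, by = "patient_id")
  present <- unique(dat$group)

  km <- purrr::map(setNames(present, present), function(g) {
    km_estimate(filter(dat, .data$group == g))
  })
  lr <- if (length(present) >= 2) logrank(dat, "group") else NULL
  cox_tbl <- NULL
  if ("neither" %in% present) {
    others <- setdiff(present, "neither")
    cox_tbl <- purrr::map(others, function(g) {
      sub <- filter(dat, .data$group %in% c(g, "neither"))
      bind_cols(tibble(group = g),
        cox_hr(sub$group == g, sub$os_months, sub$os_event))
    }) |> bind_rows()
  }

  vaf_strata <- NULL
  if (!is.null(vaf_cut) && "vaf_obs" %in% names(gmut)) {
    carrier_vaf <- gmut |>
      group_by(.data$patient_id) |>
      summarise(max_vaf = max(.data$vaf_obs), .groups = "drop") |>
      mutate(stratum = if_else(.data$max_vaf > vaf_cut, "high_vaf", "low_vaf"))
    sdat <- inner_join(carrier_vaf, clinical, by = "patient_id")
    strata_present <- unique(sdat$stratum)
    vaf_strata <- list(
      membership = select(carrier_vaf, "patient_id", "max_vaf", "stratum"),
      km = purrr::map(setNames(strata_present, strata_present), function(g) {
        km_estimate(filter(sdat, .data$stratum == g))
      }),
      logrank = if (length(strata_present) == 2) logrank(sdat, "stratum") else NULL,
      cox = if (length(strata_present) == 2) {
        cox_hr(sdat$stratum == "high_vaf", sdat$os_months, sdat$os_event)
      } else NULL
    )
  }

  list(groups = groups, km = km, logrank = lr,
    cox_vs_wildtype = cox_tbl, vaf_strata = vaf_strata)
}
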