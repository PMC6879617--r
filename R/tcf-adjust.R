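#' Estimate tumor cell fraction from observed VAF and copy-number state
#'
#' Converts an observed variant allele frequency into the estimated fraction
#' of tumor cells carrying the mutation, given the overlapping copy-number
#' state.  The branch formulas are:
#'
#' * deletion: `tcf = tcn * vaf`
#' * UPD, `vaf > 0.5 * (1 - ascn)` (UPD occurred after the mutation):
#'   `tcf = 2 * vaf - 1 + ascn`
#' * UPD, `vaf <= 0.5 * (1 - ascn)` (mutation occurred after the UPD):
#'   `tcf = 2 * vaf`
#' * neutral (no copy-number change): `tcf = 2 * vaf`
#' * gain: total copy number is fixed at 3 by convention, so
#'   `tcf = 3 * vaf`
#'
#' Values falling outside `[0, 1]` (possible for gains with `vaf > 1/3` and
#' for the late-UPD branch) are clamped, with a `clamped` flag, rather than
#' rejected: downstream clustering needs bounded prevalences.  The boundary
#' `vaf == 0.5 * (1 - ascn)` is assigned to the early-UPD branch, which is
#' continuous with the neutral case; `boundary` flags those calls for audit
#' because the two UPD branches do not agree in the limit.
#'
#' @param vaf_obs Numeric vector of observed VAFs in `[0, 1]`.
#' @param region_class Character vector: `neutral`, `deletion`, `gain`, `UPD`.
#' @param tcn Total copy number (used by the deletion branch).
#' @param ascn Minor allele-specific copy number in `[0, 1]` (UPD branches).
#' @return A tibble with columns `tcf`, `branch_used` (one of `neutral`,
#'   `deletion`, `gain`, `upd_early`, `upd_late`), `clamped`, `boundary`.
#' @seealso [vaf_expected()] for the inverse mapping, [adjust_vaf()] for the
#'   data-frame interface.
#' @export
estimate_tcf <- function(vaf_obs, region_class, tcn = 2, ascn = 1) {
  n <- length(vaf_obs)
  region_class <- rep_len(region_class, n)
  tcn <- rep_len(tcn, n)
  ascn <- rep_len(ascn, n)
  if (any(vaf_obs < 0 | vaf_obs > 1, na.rm = TRUE)) {
    stop_validation("vaf_obs must lie in [0, 1]")
  }
  if (!all(region_class %in% c("neutral", "deletion", "gain", "UPD"))) {
    stop_validation("region_class must be neutral, deletion, gain or UPD")
  }

  branch <- character(n)
  raw <- numeric(n)
  boundary <- rep(FALSE, n)

  neu <- region_class == "neutral"
  branch[neu] <- "neutral"
  raw[neu] <- 2 * vaf_obs[neu]

  del <- region_class == "deletion"
  branch[del] <- "deletion"
  raw[del] <- tcn[del] * vaf_obs[del]

  gai <- region_class == "gain"
  branch[gai] <- "gain"
  raw[gai] <- 3 * vaf_obs[gai]

  upd <- region_class == "UPD"
  if (any(upd)) {
    thr <- 0.5 * (1 - ascn[upd])
    late <- vaf_obs[upd] > thr
    b <- ifelse(late, "upd_late", "upd_early")
    r <- ifelse(late, 2 * vaf_obs[upd] - 1 + ascn[upd], 2 * vaf_obs[upd])
    branch[upd] <- b
    raw[upd] <- r
    boundary[upd] <- abs(vaf_obs[upd] - thr) < 1e-12
  }

  tcf <- pmin(pmax(raw, 0), 1)
  tibble(
    tcf = tcf,
    branch_used = branch,
    clamped = raw < 0 | raw > 1,
    boundary = boundary
  )
}

#' Expected VAF for a given cellular prevalence
#'
#' Algebraic inverse of [estimate_tcf()], used as the emission mean of the
#' clustering model: given the fraction `phi` of tumor cells carrying a
#' mutation and the copy-number branch, returns the read-level variant
#' allele fraction expected at that locus.
#'
#' * neutral / early-UPD: `phi / 2`
#' * late-UPD: `(phi + 1 - ascn) / 2`
#' * deletion: `phi / tcn`
#' * gain: `phi / 3`
#'
#' Results are clipped to `[0, 1]`.
#'
#' @param phi Cellular prevalence vector in `[0, 1]`.
#' @param branch Branch name(s): `neutral`, `upd_early`, `upd_late`,
#'   `deletion`, `gain`.
#' @param tcn Total copy number (deletion branch); must be positive.
#' @param ascn Minor allele-specific copy number (late-UPD branch).
#' @return Numeric vector of expected VAFs.
#' @export
vaf_expected <- function(phi, branch, tcn = 2, ascn = 1) {
  n <- length(phi)
  branch <- rep_len(branch, n)
  tcn <- rep_len(tcn, n)
  ascn <- rep_len(ascn, n)
  if (any(phi < 0 | phi > 1, na.rm = TRUE)) {
    stop_validation("phi must lie in [0, 1]")
  }
  if (!all(branch %in% c("neutral", "upd_early", "upd_late", "deletion", "gain"))) {
    stop_validation("unknown branch name")
  }
  if (any(branch == "deletion" & tcn <= 0)) {
    stop_validation("deletion branch requires tcn > 0")
  }
  v <- numeric(n)
  idx <- branch %in% c("neutral", "upd_early")
  v[idx] <- phi[idx] / 2
  idx <- branch == "upd_late"
  v[idx] <- (phi[idx] + 1 - ascn[idx]) / 2
  idx <- branch == "deletion"
  v[idx] <- phi[idx] / tcn[idx]
  idx <- branch == "gain"
  v[idx] <- phi[idx] / 3
  pmin(pmax(v, 0), 1)
}

#' Adjust a mutation table from VAF to tumor cell fraction
#'
#' Data-frame interface over [match_cn_state()] and [estimate_tcf()]:
#' attaches copy-number state (neutral default when no segments are given)
#' and appends `tcf`, `branch_used`, `clamped`, `boundary` columns.
#'
#' @param calls Mutation call tibble with `vaf_obs` (see
#'   [read_mutation_table()]).
#' @param segments Optional copy-number segment tibble ([read_seg()]).
#' @return The adjusted tibble.
#' @export
adjust_vaf <- function(calls, segments = NULL) {
  check_columns(calls, c("patient_id", "vaf_obs"), what = "mutation calls")
  matched <- if (all(c("region_class", "tcn", "ascn") %in% names(calls))) {
    calls
  } else {
    match_cn_state(calls, segments)
  }
  adj <- estimate_tcf(matched$vaf_obs, matched$region_class,
    matched$tcn, matched$ascn)
  bind_cols(matched, adj)
}
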