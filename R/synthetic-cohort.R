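#' Simulation configuration for synthetic MDS cohorts
#'
#' Builds the configuration object consumed by [simulate_cohort()].  The
#' defaults emulate the structure of a large targeted-sequencing MDS cohort:
#' about half of patients are single-clone (median two clones among
#' multiclonal patients, range 1-7), mean sequencing depth 796 with a wide
#' negative-binomial spread truncated at the depth-20 filter, gene usage
#' following the packaged 36-gene panel with gene-specific dominant vs
#' secondary propensities, recurrent copy-number lesions (del(5q) 16%,
#' -7/del(7q) 10%, trisomy-8-like gain, and common UPD regions), dichotomous
#' phenotypes drawn from logistic models with configurable pair effects,
#' exponential survival (baseline median 27 months) with group hazard
#' multipliers, and Bernoulli response to hypomethylating agents.
#'
#' @param n_patients Number of patients.
#' @param clone_count_weights Probability vector over 1..7 clones.
#' @param mean_depth Mean sequencing depth per mutation.
#' @param depth_dispersion Negative-binomial size parameter (smaller =
#'   wider spread).
#' @param muts_per_clone_lambda Poisson rate for extra mutations per clone
#'   (each clone carries `1 + Pois(lambda)` mutations).
#' @param gene_panel Gene panel tibble (`gene, chrom, pos, freq,
#'   dominant_share`); defaults to [gene_panel_default()].
#' @param cna_lesions Lesion tibble (`lesion, chrom, start, end,
#'   region_class, tcn, ascn, freq`).
#' @param phenotype_effects Tibble of pair effects (`dominant_gene,
#'   secondary_gene, mpn_log_or, highrisk_log_or`) added on the logit scale.
#' @param mpn_base_prob Baseline probability of the MDS/MPN phenotype.
#' @param highrisk_base_prob Baseline probability of the high-risk group.
#' @param saml_prob Fraction of patients recorded as sAML (mapped back to
#'   their antecedent MDS or MDS/MPN class for phenotype dichotomies).
#' @param survival_base_rate Baseline exponential event rate per month.
#' @param hazard_ratios Named list of hazard multipliers; recognized names
#'   are `"<GENE>:dominant"`, `"<GENE>:secondary"`, `"high_risk"`, `"ch_u"`.
#' @param censor_max Upper bound of the independent uniform censoring time.
#' @param hma_treated_frac Fraction of patients treated with HMA.
#' @param hma_base_prob Baseline HMA response probability.
#' @param hma_effects Named list of per-gene response log-odds.
#' @param error_rate Sequencing error floor on expected VAFs.
#' @param excluded_frac Fraction of calls flagged as indel/repetitive
#'   (withheld from clustering, labeled post hoc).
#' @param unidirectional_frac Fraction of calls lacking bidirectional
#'   support (removed by [filter_variants()]).
#' @param branching Allow one branching event instead of a strictly linear
#'   chain (exercises prevalence tie-breaking); default `FALSE`.
#' @param seed Integer seed; the full cohort is reproducible bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_patients = 300,
    clone_count_weights = c(0.525, 0.26, 0.12, 0.055, 0.025, 0.01, 0.005),
    mean_depth = 796,
    depth_dispersion = 3,
    muts_per_clone_lambda = 0.35,
    gene_panel = gene_panel_default(),
    cna_lesions = cna_lesions_default(),
    phenotype_effects = phenotype_effects_default(),
    mpn_base_prob = 0.125,
    highrisk_base_prob = 0.42,
    saml_prob = 0.08,
    survival_base_rate = log(2) / 27,
    hazard_ratios = list("TP53:dominant" = 2.9, "TP53:secondary" = 1.5,
      high_risk = 1.8, ch_u = 1.45),
    censor_max = 120,
    hma_treated_frac = 0.10,
    hma_base_prob = 0.30,
    hma_effects = list(TET2 = log(2.4), ASXL1 = log(0.45)),
    error_rate = 0.001,
    excluded_frac = 0.05,
    unidirectional_frac = 0.02,
    branching = FALSE,
    seed = 1L) {
  if (n_patients < 1) stop_config("n_patients must be positive")
  w <- clone_count_weights
  if (length(w) != 7 || any(w < 0) || sum(w) <= 0) {
    stop_validation("clone_count_weights must be 7 non-negative weights with positive sum")
  }
  w <- w / sum(w)
  if (mean_depth <= 0 || depth_dispersion <= 0) {
    stop_config("depth parameters must be positive")
  }
  check_columns(gene_panel, c("gene", "chrom", "pos", "freq", "dominant_share"),
    what = "gene panel")
  structure(list(
    n_patients = as.integer(n_patients),
    clone_count_weights = w,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    muts_per_clone_lambda = muts_per_clone_lambda,
    gene_panel = gene_panel,
    cna_lesions = cna_lesions,
    phenotype_effects = phenotype_effects,
    mpn_base_prob = mpn_base_prob,
    highrisk_base_prob = highrisk_base_prob,
    saml_prob = saml_prob,
    survival_base_rate = survival_base_rate,
    hazard_ratios = hazard_ratios,
    censor_max = censor_max,
    hma_treated_frac = hma_treated_frac,
    hma_base_prob = hma_base_prob,
    hma_effects = hma_effects,
    error_rate = error_rate,
    excluded_frac = excluded_frac,
    unidirectional_frac = unidirectional_frac,
    branching = isTRUE(branching),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default simulated copy-number lesions
#'
#' Recurrent myeloid lesions with cohort frequencies: del(5q) 16%,
#' -7/del(7q) 10%, a chromosome-8 gain, and UPD at 4q, 11q, 9p (regions
#' containing TET2, CBL, JAK2).  Coordinates are synthetic anchors matching
#' the packaged gene panel.
#'
#' @return A tibble with one row per lesion.
#' @export
cna_lesions_default <- function() {
  tibble(
    lesion = c("del5q", "del7q", "gain8", "upd4q", "upd11q", "upd9p"),
    chrom = c("5", "7", "8", "4", "11", "9"),
    start = c(1e8, 6e7, 1, 5e7, 6e7, 1),
    end = c(1.8e8, 1.59e8, 1.46e8, 1.9e8, 1.35e8, 4e7),
    region_class = c("deletion", "deletion", "gain", "UPD", "UPD", "UPD"),
    tcn = c(1, 1, 3, 2, 2, 2),
    ascn = c(0, 0, 1, 0, 0, 0),
    freq = c(0.16, 0.10, 0.05, 0.04, 0.03, 0.02)
  )
}

#' Default phenotype pair effects
#'
#' Log-odds added when a patient carries the given dominant/secondary gene
#' pair: a dominant-TET2 + secondary-SRSF2 combination pushes toward the
#' MDS/MPN phenotype, dominant RUNX1 + secondary ASXL1 toward high risk,
#' and dominant SF3B1 + secondary DNMT3A or JAK2 toward low risk (JAK2 also
#' toward MDS/MPN).
#'
#' @return A tibble of pair effects.
#' @export
phenotype_effects_default <- function() {
  tibble(
    dominant_gene = c("TET2", "RUNX1", "SF3B1", "SF3B1"),
    secondary_gene = c("SRSF2", "ASXL1", "DNMT3A", "JAK2"),
    mpn_log_or = c(1.7, 0, 0, 1.2),
    highrisk_log_or = c(0.7, 1.2, -1.0, -1.0)
  )
}

# negative-binomial depths truncated at the depth filter (>= 20)
sample_depths <- function(n, mu, size, min_depth = 20) {
  d <- rnbinom(n, mu = mu, size = size)
  while (any(d < min_depth)) {
    i <- d < min_depth
    d[i] <- rnbinom(sum(i), mu = mu, size = size)
  }
  as.integer(d)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws, per patient: a clone count, nested cellular prevalences (each
#' child clone no larger than its parent), mutations assigned to clones
#' with gene propensities conditioned on rank, read depths from a truncated
#' negative binomial, alt reads from a binomial at the copy-number-aware
#' expected VAF ([vaf_expected()]), copy-number lesions, phenotype labels
#' from logistic models with configured pair effects, exponential survival
#' with group hazards and independent uniform censoring, and Bernoulli HMA
#' response.  Fully reproducible under the config seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `synthetic_cohort` with elements `mutations`,
#'   `clinical`, `cn_segments` (the cohort tables) and `truth` (clone
#'   prevalences, per-mutation clone/rank labels, per-patient phenotype,
#'   CH category and hazards).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must come from sim_config()")
  set.seed(config$seed)
  panel <- config$gene_panel
  lesions <- config$cna_lesions

  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  # --- copy-number lesions per patient ------------------------------------
  seg_list <- list()
  for (j in seq_len(nrow(lesions))) {
    carrier <- runif(n) < lesions$freq[j]
    if (any(carrier)) {
      seg_list[[length(seg_list) + 1]] <- tibble(
        patient_id = pid[carrier],
        chrom = lesions$chrom[j], start = lesions$start[j],
        end = lesions$end[j], region_class = lesions$region_class[j],
        tcn = lesions$tcn[j], ascn = lesions$ascn[j]
      )
    }
  }
  cn_segments <- if (length(seg_list) > 0) bind_rows(seg_list) else
    tibble(patient_id = character(), chrom = character(), start = numeric(),
      end = numeric(), region_class = character(), tcn = numeric(),
      ascn = numeric())

  # --- clonal structure and mutations -------------------------------------
  w_dom <- panel$freq * panel$dominant_share
  w_sec <- panel$freq * (1 - panel$dominant_share)
  if (sum(w_sec) <= 0) w_sec <- panel$freq

  clones_list <- vector("list", n)
  mut_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample.int(7, 1, prob = config$clone_count_weights)
    # nested prevalences: linear chain (optionally one branching event)
    prev <- numeric(k)
    prev[1] <- rbeta(1, 8, 2)
    if (k > 1) {
      branch_at <- if (config$branching && k >= 3) sample(2:k, 1) else 0L
      for (cl in 2:k) {
        parent <- if (cl == branch_at) prev[cl - 2 + (cl == 2)] else prev[cl - 1]
        prev[cl] <- parent * rbeta(1, 5, 3)
      }
      prev <- sort(prev, decreasing = TRUE)
    }
    clones_list[[i]] <- tibble(patient_id = pid[i],
      clone = seq_len(k), prevalence = prev)

    pm <- vector("list", k)
    for (cl in seq_len(k)) {
      m_cl <- 1L + rpois(1, config$muts_per_clone_lambda)
      wts <- if (cl == 1) w_dom else w_sec
      g <- sample(panel$gene, m_cl, replace = FALSE, prob = wts)
      pm[[cl]] <- tibble(gene = g, clone = cl, prevalence = prev[cl])
    }
    muts <- bind_rows(pm)
    muts$patient_id <- pid[i]
    mut_list[[i]] <- muts
  }
  truth_clones <- bind_rows(clones_list)
  mutations <- bind_rows(mut_list) |>
    left_join(select(panel, "gene", "chrom", "pos"), by = "gene") |>
    mutate(
      pos = .data$pos + sample.int(1000, n(), replace = TRUE) - 1,
      ref = sample(c("A", "C", "G", "T"), n(), replace = TRUE),
      variant_class = sample(
        c("missense", "truncating", "splice", "canonical_hotspot"),
        n(), replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)
      )
    )
  mutations$alt <- vapply(mutations$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))

  # --- read counts via copy-number-aware expected VAF ---------------------
  mutations <- match_cn_state(mutations, cn_segments)
  # genotype relative to a UPD region: if the mutation sits inside a UPD,
  # decide whether the mutation preceded the UPD (duplicated, late branch)
  # or arose after it (heterozygous, early branch)
  in_upd <- mutations$region_class == "UPD"
  upd_late <- in_upd & runif(nrow(mutations)) < 0.5
  branch <- dplyr::case_when(
    mutations$region_class == "deletion" ~ "deletion",
    mutations$region_class == "gain" ~ "gain",
    upd_late ~ "upd_late",
    in_upd ~ "upd_early",
    TRUE ~ "neutral"
  )
  v_exp <- vaf_expected(mutations$prevalence, branch,
    mutations$tcn, mutations$ascn)
  v_exp <- pmin(pmax(v_exp, config$error_rate), 1 - config$error_rate)
  depth <- sample_depths(nrow(mutations), config$mean_depth,
    config$depth_dispersion)
  alt_reads <- rbinom(nrow(mutations), depth, v_exp)

  within_idx <- stats::ave(seq_len(nrow(mutations)), mutations$patient_id,
    FUN = seq_along)
  mut_id <- sprintf("%s:%s:%d:%d", mutations$patient_id, mutations$chrom,
    as.integer(mutations$pos), within_idx)
  truth_mutations <- tibble(
    mut_id = mut_id,
    patient_id = mutations$patient_id,
    gene = mutations$gene,
    true_clone = mutations$clone,
    true_prevalence = mutations$prevalence,
    true_label = if_else(mutations$clone == 1L, "dominant", "secondary"),
    true_branch = branch,
    expected_vaf = v_exp
  )

  mutations_out <- tibble(
    mut_id = mut_id,
    patient_id = mutations$patient_id,
    gene = mutations$gene,
    variant_class = mutations$variant_class,
    chrom = mutations$chrom,
    pos = as.numeric(mutations$pos),
    ref = mutations$ref,
    alt = mutations$alt,
    alt_reads = alt_reads,
    depth = depth,
    vaf_obs = alt_reads / depth,
    bidirectional = runif(nrow(mutations)) >= config$unidirectional_frac,
    excluded = runif(nrow(mutations)) < config$excluded_frac
  )

  # --- phenotypes ----------------------------------------------------------
  dom_genes <- truth_mutations |>
    filter(.data$true_label == "dominant") |>
    distinct(.data$patient_id, .data$gene)
  sec_genes <- truth_mutations |>
    filter(.data$true_label == "secondary") |>
    distinct(.data$patient_id, .data$gene)

  has_pair <- function(dom_g, sec_g) {
    pid_d <- dom_genes$patient_id[dom_genes$gene == dom_g]
    pid_s <- sec_genes$patient_id[sec_genes$gene == sec_g]
    pid %in% intersect(pid_d, pid_s)
  }
  mpn_lo <- rep(stats::qlogis(config$mpn_base_prob), n)
  hr_lo <- rep(stats::qlogis(config$highrisk_base_prob), n)
  pe <- config$phenotype_effects
  for (j in seq_len(nrow(pe))) {
    hit <- has_pair(pe$dominant_gene[j], pe$secondary_gene[j])
    mpn_lo <- mpn_lo + pe$mpn_log_or[j] * hit
    hr_lo <- hr_lo + pe$highrisk_log_or[j] * hit
  }
  is_mpn <- runif(n) < stats::plogis(mpn_lo)
  high_risk <- runif(n) < stats::plogis(hr_lo)
  ipssr <- if_else(high_risk, runif(n, 3.6, 9), runif(n, 0.5, 3.5))
  is_saml <- runif(n) < config$saml_prob
  diagnosis <- dplyr::case_when(
    is_saml ~ "sAML",
    is_mpn ~ "MDS_MPN",
    TRUE ~ "MDS"
  )
  antecedent <- if_else(is_saml, if_else(is_mpn, "MDS_MPN", "MDS"),
    NA_character_)

  # --- CH category from true dominant genes --------------------------------
  ch_class <- unname(vapply(pid, function(p) {
    g <- dom_genes$gene[dom_genes$patient_id == p]
    classify_dominant_genes(g)
  }, character(1)))

  # --- survival -------------------------------------------------------------
  hazard <- rep(config$survival_base_rate, n)
  hr_cfg <- config$hazard_ratios
  for (nm in names(hr_cfg)) {
    mult <- hr_cfg[[nm]]
    hit <- switch(nm,
      high_risk = high_risk,
      ch_u = ch_class == "CH_U",
      {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        tab <- if (identical(parts[2], "dominant")) dom_genes else sec_genes
        pid %in% tab$patient_id[tab$gene == parts[1]]
      }
    )
    hazard <- hazard * ifelse(hit, mult, 1)
  }
  t_event <- rexp(n, hazard)
  t_cens <- runif(n, 0, config$censor_max)
  os_months <- pmin(t_event, t_cens)
  os_event <- t_event <= t_cens

  # --- HMA therapy ----------------------------------------------------------
  hma_treated <- runif(n) < config$hma_treated_frac
  resp_lo <- rep(stats::qlogis(config$hma_base_prob), n)
  mut_genes <- distinct(truth_mutations, .data$patient_id, .data$gene)
  for (g in names(config$hma_effects)) {
    hit <- pid %in% mut_genes$patient_id[mut_genes$gene == g]
    resp_lo <- resp_lo + config$hma_effects[[g]] * hit
  }
  responder <- hma_treated & runif(n) < stats::plogis(resp_lo)
  hma_response <- rep(NA_character_, n)
  hma_response[hma_treated & !responder] <- "none"
  resp_idx <- which(responder)
  if (length(resp_idx) > 0) {
    hma_response[resp_idx] <- sample(c("CR", "PR", "HI"),
      length(resp_idx), replace = TRUE, prob = c(0.5, 0.25, 0.25))
  }

  clinical <- tibble(
    patient_id = pid,
    diagnosis = diagnosis,
    antecedent = antecedent,
    ipssr_score = round(ipssr, 1),
    os_months = round(os_months, 2),
    os_event = os_event,
    hma_treated = hma_treated,
    hma_response = hma_response
  ) |>
    derive_risk_group()

  truth_patients <- tibble(
    patient_id = pid,
    n_clones = purrr::map_int(clones_list, nrow),
    is_mpn = is_mpn,
    high_risk = high_risk,
    ch_class = ch_class,
    hazard = hazard,
    t_event = t_event
  )

  structure(list(
    mutations = mutations_out,
    clinical = clinical,
    cn_segments = cn_segments,
    truth = list(
      clones = truth_clones,
      mutations = truth_mutations,
      patients = truth_patients
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d mutations, %d CN segments (seed %d)\n",
    nrow(x$clinical), nrow(x$mutations), nrow(x$cn_segments), x$config$seed
  ))
  invisible(x)
}

#' Check simulated read counts against their expected VAFs
#'
#' For every simulated clone, compares the mean observed VAF of its
#' mutations with the copy-number-aware expected VAF implied by the clone's
#' true prevalence, and lists violations beyond the tolerance.
#'
#' @param sim A [simulate_cohort()] result.
#' @param tol Absolute tolerance on the clone-level mean (default 0.05).
#' @return A tibble with one row per (patient, clone, branch) group:
#'   number of mutations, mean expected and observed VAF, deviation and an
#'   `ok` flag.
#' @export
expected_vaf_sanity <- function(sim, tol = 0.05) {
  if (!inherits(sim, "synthetic_cohort")) {
    stop_validation("expected_vaf_sanity() needs a matched synthetic_cohort object")
  }
  obs <- select(sim$mutations, "mut_id", "vaf_obs", "depth")
  joined <- inner_join(sim$truth$mutations, obs, by = "mut_id")
  if (nrow(joined) != nrow(sim$mutations)) {
    stop_validation("mutation identifiers do not match between cohort and truth")
  }
  joined |>
    group_by(.data$patient_id, .data$true_clone, .data$true_branch) |>
    summarise(
      n = n(),
      mean_expected = mean(.data$expected_vaf),
      mean_observed = mean(.data$vaf_obs),
      .groups = "drop"
    ) |>
    mutate(
      deviation = .data$mean_observed - .data$mean_expected,
      ok = abs(.data$deviation) <= tol
    )
}
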