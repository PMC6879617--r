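#' Fisher's exact test for 2x2 tables with the cross-product odds ratio
#'
#' Two-sided exact p-value for a 2x2 contingency table with fixed margins:
#' the sum of hypergeometric probabilities of all tables no more probable
#' than the observed one (point-probability criterion, with the standard
#' `1 + 1e-7` relative slack against ties in floating point).  The reported
#' odds ratio is the sample cross-product `(a*d)/(b*c)`, with `Inf` when
#' `b*c == 0` and `a*d > 0` (and 0 when `a*d == 0 < b*c`); this matches how
#' published cohort tables report degenerate pairs, unlike the
#' conditional-MLE estimator.  The conditional MLE is available via
#' `estimator = "cmle"` for cross-checking.
#'
#' All arguments are vectorized.
#'
#' @param a,b,c,d Non-negative integer cell counts; the table is
#'   `rbind(c(a, b), c(c, d))`.
#' @param estimator `"cross_product"` (default) or `"cmle"` (conditional
#'   maximum likelihood, as returned by [stats::fisher.test()]).
#' @return A tibble with columns `odds_ratio` and `p`.
#' @export
fisher_2x2 <- function(a, b, c, d, estimator = c("cross_product", "cmle")) {
  estimator <- match.arg(estimator)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop_validation("cell counts must be non-negative")
  }
  if (any(a + b + c + d == 0)) {
    stop_validation("all-zero 2x2 table")
  }
  p <- vapply(seq_len(n), function(i) {
    fisher_p_twosided(a[i], b[i], c[i], d[i])
  }, numeric(1))
  or <- if (estimator == "cross_product") {
    ifelse(b * c == 0,
      ifelse(a * d == 0, NaN, Inf),
      (a * d) / (b * c))
  } else {
    vapply(seq_len(n), function(i) {
      unname(stats::fisher.test(matrix(c(a[i], c[i], b[i], d[i]), 2))$estimate)
    }, numeric(1))
  }
  tibble(odds_ratio = or, p = p)
}

# two-sided p for a single table: hypergeometric enumeration over the
# support of cell `a` given fixed margins
fisher_p_twosided <- function(a, b, c, d) {
  m <- a + b      # row-1 margin
  nn <- c + d     # row-2 margin
  k <- a + c      # column-1 margin
  lo <- max(0, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, nn, k)
  obs <- dhyper(a, m, nn, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, capped at 1, returned in the
#' input order.  Permutation-invariant and elementwise `>= p`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p[ord]))
  q[order(ord)]
}

#' Dominant-to-secondary pair association tables
#'
#' For every gene X recurrently dominant (in more than `min_dom_freq` of
#' patients, strict) and every gene Y recurrently secondary (more than
#' `min_sec_freq`), builds the 2x2 table over all patients:
#' a = X dominant AND Y secondary, b = X dominant without Y secondary,
#' c = Y secondary without X dominant, d = neither; then Fisher tests with
#' BH correction over all tested pairs as one family.
#'
#' @param architecture Labeled architecture tibble (`patient_id, gene,
#'   label`), one row per mutation.
#' @param min_dom_freq,min_sec_freq Strict patient-fraction thresholds for
#'   a gene to enter the dominant / secondary test set (default 1%).
#' @param q_co Significance threshold on q for flagging (default 0.01).
#' @param n_patients Optional cohort size; defaults to the number of
#'   distinct patients in `architecture` (supply it when mutation-free
#'   patients exist).
#' @param estimator Odds-ratio estimator, see [fisher_2x2()].
#' @return A tibble with one row per tested pair: the four counts
#'   (`co_occurrence, dominant_only, secondary_only, intact`), `odds_ratio`,
#'   `p`, `q`, `direction` (`co_occurrence` if OR > 1 else
#'   `mutual_exclusivity`) and `significant`.
#' @export
pair_tables <- function(architecture, min_dom_freq = 0.01,
                        min_sec_freq = 0.01, q_co = 0.01,
                        n_patients = NULL,
                        estimator = c("cross_product", "cmle")) {
  estimator <- match.arg(estimator)
  check_columns(architecture, c("patient_id", "gene", "label"),
    what = "architecture")
  if (nrow(architecture) == 0) stop_validation("empty cohort")
  patients <- unique(architecture$patient_id)
  n_total <- if (is.null(n_patients)) length(patients) else as.integer(n_patients)

  dom <- architecture |>
    filter(.data$label == "dominant") |>
    distinct(.data$patient_id, .data$gene)
  sec <- architecture |>
    filter(.data$label == "secondary") |>
    distinct(.data$patient_id, .data$gene)

  dom_genes <- dom |> count(.data$gene) |>
    filter(.data$n / n_total > min_dom_freq) |> pull("gene")
  sec_genes <- sec |> count(.data$gene) |>
    filter(.data$n / n_total > min_sec_freq) |> pull("gene")
  if (length(dom_genes) == 0 || length(sec_genes) == 0) {
    return(tibble(
      dominant = character(), secondary = character(),
      co_occurrence = integer(), dominant_only = integer(),
      secondary_only = integer(), intact = integer(),
      odds_ratio = numeric(), p = numeric(), q = numeric(),
      direction = character(), significant = logical()
    ))
  }

  grid <- tidyr::expand_grid(dominant = dom_genes, secondary = sec_genes)
  counts <- purrr::pmap(grid, function(dominant, secondary) {
    pd <- dom$patient_id[dom$gene == dominant]
    ps <- sec$patient_id[sec$gene == secondary]
    a <- length(intersect(pd, ps))
    b <- length(pd) - a
    c_ <- length(ps) - a
    tibble(co_occurrence = a, dominant_only = b, secondary_only = c_,
      intact = n_total - a - b - c_)
  }) |> bind_rows()
  out <- bind_cols(grid, counts)
  ft <- fisher_2x2(out$co_occurrence, out$dominant_only,
    out$secondary_only, out$intact, estimator = estimator)
  out |>
    mutate(
      odds_ratio = ft$odds_ratio,
      p = ft$p,
      q = bh_adjust(ft$p),
      direction = if_else(.data$odds_ratio > 1, "co_occurrence",
        "mutual_exclusivity"),
      significant = .data$q < q_co
    )
}

#' Pairwise lesion correlation (co-occurrence / mutual exclusivity)
#'
#' Presence/absence association between all frequent genetic lesions
#' (mutated genes and copy-number lesions) over patients: Fisher tests on
#' the pairwise 2x2 tables, BH correction, with the asymmetric significance
#' convention — coexistence flagged at `q < q_co` (default 0.01) and
#' exclusivity at `q < q_ex` (default 0.25).
#'
#' @param lesions Tibble `patient_id, lesion` (one row per patient-lesion;
#'   build from mutations and CN segments).
#' @param n_patients Cohort size (defaults to distinct patients present).
#' @param min_freq Strict frequency threshold for a lesion to be tested
#'   (default 2%).
#' @param q_co,q_ex Significance thresholds for coexistence / exclusion.
#' @return A tibble with one row per unordered lesion pair and columns as
#'   in [pair_tables()] plus `significant` per the asymmetric rule.
#' @export
lesion_correlation <- function(lesions, n_patients = NULL, min_freq = 0.02,
                               q_co = 0.01, q_ex = 0.25) {
  check_columns(lesions, c("patient_id", "lesion"), what = "lesions")
  les <- distinct(lesions, .data$patient_id, .data$lesion)
  n_total <- if (is.null(n_patients)) length(unique(les$patient_id)) else
    as.integer(n_patients)
  keep <- les |> count(.data$lesion) |>
    filter(.data$n / n_total > min_freq) |> pull("lesion")
  keep <- sort(keep)
  if (length(keep) < 2) {
    return(tibble(lesion_a = character(), lesion_b = character()))
  }
  pairs <- utils::combn(keep, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    la <- pairs[1, j]; lb <- pairs[2, j]
    pa <- les$patient_id[les$lesion == la]
    pb <- les$patient_id[les$lesion == lb]
    a <- length(intersect(pa, pb))
    b <- length(pa) - a
    c_ <- length(pb) - a
    tibble(lesion_a = la, lesion_b = lb, both = a, a_only = b, b_only = c_,
      neither = n_total - a - b - c_)
  })
  out <- bind_rows(rows)
  ft <- fisher_2x2(out$both, out$a_only, out$b_only, out$neither)
  out |>
    mutate(
      odds_ratio = ft$odds_ratio,
      p = ft$p,
      q = bh_adjust(ft$p),
      direction = if_else(.data$odds_ratio > 1, "co_occurrence",
        "mutual_exclusivity"),
      significant = if_else(.data$direction == "co_occurrence",
        .data$q < q_co, .data$q < q_ex)
    )
}

# Woolf logit CI with Haldane 0.5 correction applied only to the CI,
# never to the point estimate
woolf_ci <- function(a, b, c, d, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  ah <- a + 0.5; bh <- b + 0.5; ch <- c + 0.5; dh <- d + 0.5
  log_or <- log(ah * dh / (bh * ch))
  se <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
  tibble(
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    ci_non_estimable = (a == 0 & b == 0) | (c == 0 & d == 0) |
      (a == 0 & c == 0) | (b == 0 & d == 0)
  )
}

#' Phenotype odds ratios for lesions, ranks, or dominant/secondary pairs
#'
#' For each tested group, builds the 2x2 table of group membership against
#' a dichotomous phenotype and reports the cross-product odds ratio, Woolf
#' 95% confidence interval (Haldane-corrected for the CI only), Fisher p
#' and BH q.  Groupings:
#'
#' * `single_lesion` — patients carrying any mutation in the gene;
#' * `dominant_only` / `secondary_only` — carriers of the gene at that rank;
#' * `pair_both_vs_neither` — patients with both dominant X and secondary Y
#'   versus patients with neither (partial carriers are dropped from the
#'   table), the published three-step procedure for pair effects.
#'
#' Phenotypes: `"mpn"` compares MDS vs MDS/MPN (sAML patients enter by
#' their antecedent class when an `antecedent` column is present) and
#' `"risk"` compares low vs high risk.  The odds ratio is oriented so that
#' values above 1 mean enrichment of the second level (MDS/MPN, high risk)
#' among carriers.
#'
#' @param architecture Labeled architecture tibble.
#' @param clinical Clinical tibble with `diagnosis`, `risk_group` (and
#'   optionally `antecedent`).
#' @param grouping One of `single_lesion`, `dominant_only`,
#'   `secondary_only`, `pair_both_vs_neither`.
#' @param phenotype `"mpn"` or `"risk"`.
#' @param genes Genes (or for pairs, a tibble `dominant, secondary`) to
#'   test; defaults to all genes present at the relevant rank.
#' @return A tibble with counts, `odds_ratio`, `ci_low`, `ci_high`, `p`,
#'   `q` and `ci_non_estimable`.
#' @export
phenotype_or <- function(architecture, clinical,
                         grouping = c("single_lesion", "dominant_only",
                           "secondary_only", "pair_both_vs_neither"),
                         phenotype = c("mpn", "risk"),
                         genes = NULL) {
  grouping <- match.arg(grouping)
  phenotype <- match.arg(phenotype)
  check_columns(clinical, c("patient_id", "diagnosis", "risk_group"),
    what = "clinical")

  pheno <- phenotype_indicator(clinical, phenotype)
  pos_ids <- pheno$patient_id[pheno$positive]

  if (grouping == "pair_both_vs_neither") {
    dom <- architecture |> filter(.data$label == "dominant") |>
      distinct(.data$patient_id, .data$gene)
    sec <- architecture |> filter(.data$label == "secondary") |>
      distinct(.data$patient_id, .data$gene)
    if (is.null(genes)) {
      genes <- tidyr::expand_grid(
        dominant = unique(dom$gene), secondary = unique(sec$gene))
    }
    rows <- purrr::pmap(genes, function(dominant, secondary, ...) {
      pd <- dom$patient_id[dom$gene == dominant]
      ps <- sec$patient_id[sec$gene == secondary]
      both <- intersect(pd, ps)
      neither <- setdiff(pheno$patient_id, union(pd, ps))
      a <- sum(both %in% pos_ids)
      b <- length(intersect(both, pheno$patient_id)) - a
      c_ <- sum(neither %in% pos_ids)
      d <- length(neither) - c_
      tibble(dominant = dominant, secondary = secondary,
        a = a, b = b, c = c_, d = d)
    })
    out <- bind_rows(rows)
  } else {
    carriers <- switch(grouping,
      single_lesion = distinct(architecture, .data$patient_id, .data$gene),
      dominant_only = architecture |> filter(.data$label == "dominant") |>
        distinct(.data$patient_id, .data$gene),
      secondary_only = architecture |> filter(.data$label == "secondary") |>
        distinct(.data$patient_id, .data$gene)
    )
    if (is.null(genes)) genes <- sort(unique(carriers$gene))
    rows <- purrr::map(genes, function(g) {
      pg <- intersect(carriers$patient_id[carriers$gene == g],
        pheno$patient_id)
      rest <- setdiff(pheno$patient_id, pg)
      a <- sum(pg %in% pos_ids)
      b <- length(pg) - a
      c_ <- sum(rest %in% pos_ids)
      d <- length(rest) - c_
      tibble(gene = g, a = a, b = b, c = c_, d = d)
    })
    out <- bind_rows(rows)
  }
  if (nrow(out) == 0) return(out)
  ft <- fisher_2x2(out$a, out$b, out$c, out$d)
  ci <- woolf_ci(out$a, out$b, out$c, out$d)
  bind_cols(out, tibble(odds_ratio = ft$odds_ratio), ci,
    tibble(p = ft$p)) |>
    mutate(q = bh_adjust(.data$p))
}

# positive = second phenotype level (MDS/MPN, or high risk); sAML patients
# map to their antecedent class for the morphology dichotomy
phenotype_indicator <- function(clinical, phenotype) {
  if (phenotype == "risk") {
    return(tibble(
      patient_id = clinical$patient_id,
      positive = clinical$risk_group == "high"
    ))
  }
  diag <- clinical$diagnosis
  if ("antecedent" %in% names(clinical)) {
    saml <- diag == "sAML" & !is.na(clinical$antecedent)
    diag[saml] <- clinical$antecedent[saml]
  }
  keep <- diag %in% c("MDS", "MDS_MPN")
  tibble(
    patient_id = clinical$patient_id[keep],
    positive = diag[keep] == "MDS_MPN"
  )
}

#' Associations with response to hypomethylating therapy
#'
#' Restricts to HMA-treated patients, defines responders as complete
#' response, partial response or hematologic improvement, and tests each
#' requested group (gene carriers at any rank, or dominant-only /
#' secondary-only carriers) for association with response and with
#' complete response, via Fisher tests with cross-product odds ratios and
#' Woolf CIs.
#'
#' @param architecture Labeled architecture tibble.
#' @param clinical Clinical tibble with `hma_treated` and `hma_response`.
#' @param genes Genes to test (default: all genes mutated among treated
#'   patients).
#' @param rank `"any"`, `"dominant"` or `"secondary"` carrier definition.
#' @return A tibble with one row per gene and outcome
#'   (`responder`, `cr`): counts, odds ratio, CI, `p`, `q`.
#' @export
hma_association <- function(architecture, clinical, genes = NULL,
                            rank = c("any", "dominant", "secondary")) {
  rank <- match.arg(rank)
  check_columns(clinical, c("patient_id", "hma_treated", "hma_response"),
    what = "clinical")
  treated <- filter(clinical, .data$hma_treated)
  if (nrow(treated) == 0) stop_validation("no HMA-treated patients")
  responder <- treated$hma_response %in% c("CR", "PR", "HI")
  cr <- treated$hma_response %in% "CR"

  carriers <- switch(rank,
    any = architecture,
    dominant = filter(architecture, .data$label == "dominant"),
    secondary = filter(architecture, .data$label == "secondary")
  ) |> distinct(.data$patient_id, .data$gene)
  carriers <- filter(carriers, .data$patient_id %in% treated$patient_id)
  if (is.null(genes)) genes <- sort(unique(carriers$gene))

  rows <- purrr::map(genes, function(g) {
    has <- treated$patient_id %in%
      carriers$patient_id[carriers$gene == g]
    purrr::map(c(responder = "responder", cr = "cr"), function(oc) {
      y <- if (oc == "responder") responder else cr
      a <- sum(has & y); b <- sum(has & !y)
      c_ <- sum(!has & y); d <- sum(!has & !y)
      ft <- fisher_2x2(a, b, c_, d)
      ci <- woolf_ci(a, b, c_, d)
      bind_cols(
        tibble(gene = g, outcome = oc, a = a, b = b, c = c_, d = d,
          odds_ratio = ft$odds_ratio, p = ft$p),
        ci
      )
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  out |>
    group_by(.data$outcome) |>
    mutate(q = bh_adjust(.data$p)) |>
    ungroup()
}
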