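#' Gene sets for clonal-hematopoiesis classification
#'
#' The default sets follow the comparison of dominant-mutation spectra
#' between MDS and healthy clonal hematopoiesis (CH) cohorts: DNMT3A, TET2,
#' ASXL1 and JAK2 are markedly more frequent in CH (CH-related set), while
#' TP53, SF3B1, SRSF2, GNB1 and CBL occur at similar frequencies in both
#' (overlapping set).  Any other dominantly mutated gene marks the patient
#' as CH-unrelated.
#'
#' @param ch_related Character vector of CH-related genes.
#' @param overlapping Character vector of overlapping genes.
#' @return A list of class `ch_gene_sets`; the two sets must be disjoint.
#' @export
ch_gene_sets <- function(
    ch_related = c("DNMT3A", "TET2", "ASXL1", "JAK2"),
    overlapping = c("TP53", "SF3B1", "SRSF2", "GNB1", "CBL")) {
  ch_related <- toupper(ch_related)
  overlapping <- toupper(overlapping)
  if (length(intersect(ch_related, overlapping)) > 0) {
    stop_validation("CH-related and overlapping gene sets must be disjoint")
  }
  structure(list(ch_related = ch_related, overlapping = overlapping),
    class = "ch_gene_sets")
}

# scalar rule on a patient's dominant gene set; precedence: any CH-related
# dominant gene => CH_R; else any gene outside both sets => CH_U; else
# (all dominant genes overlapping, or no mutations) => Overlapping.
classify_dominant_genes <- function(genes, sets = ch_gene_sets()) {
  genes <- unique(toupper(genes))
  if (length(genes) == 0) return("Overlapping")
  if (any(genes %in% sets$ch_related)) return("CH_R")
  if (all(genes %in% sets$overlapping)) return("Overlapping")
  "CH_U"
}

#' Classify patients as CH-related, CH-unrelated or overlapping MDS
#'
#' Applies the dominant-gene rule to every patient of a labeled clonal
#' architecture: patients with any CH-related dominant gene are `CH_R`;
#' patients whose dominant genes all belong to the overlapping set (or who
#' have no mutations at all) are `Overlapping`; everyone else is `CH_U`.
#' Only dominant mutations matter; secondary mutations never change the
#' class.  Patients present in `patient_ids` but absent from the
#' architecture (no mutations) are classified `Overlapping`.
#'
#' @param architecture Labeled architecture tibble from
#'   [infer_architecture()] (columns `patient_id, gene, label`).
#' @param sets A [ch_gene_sets()] object.
#' @param patient_ids Optional character vector of all cohort patients, so
#'   mutation-free patients are included.
#' @return A tibble `patient_id, ch_class, mixed_overlap` where
#'   `mixed_overlap` flags patients whose dominant genes span the
#'   overlapping set and a CH-unrelated gene (classified `CH_U` by the
#'   precedence rule).
#' @export
classify_ch <- function(architecture, sets = ch_gene_sets(),
                        patient_ids = NULL) {
  check_columns(architecture, c("patient_id", "gene", "label"),
    what = "architecture")
  dom <- architecture |>
    filter(.data$label == "dominant") |>
    group_by(.data$patient_id) |>
    summarise(genes = list(unique(toupper(.data$gene))), .groups = "drop")
  res <- dom |>
    mutate(
      ch_class = purrr::map_chr(.data$genes, classify_dominant_genes, sets = sets),
      mixed_overlap = purrr::map_lgl(.data$genes, function(g) {
        any(g %in% sets$overlapping) &&
          any(!g %in% c(sets$overlapping, sets$ch_related))
      })
    ) |>
    select("patient_id", "ch_class", "mixed_overlap")
  if (!is.null(patient_ids)) {
    missing <- setdiff(patient_ids, res$patient_id)
    if (length(missing) > 0) {
      res <- bind_rows(res, tibble(
        patient_id = missing, ch_class = "Overlapping", mixed_overlap = FALSE
      ))
    }
    res <- res[match(patient_ids, res$patient_id), ]
  }
  res
}

#' Profile CH-related vs CH-unrelated patients
#'
#' Cohort-level comparison of the CH classes: class sizes and fractions,
#' dominant-gene composition per class, secondary-gene frequencies in CH-R
#' vs CH-U with Fisher tests and BH correction, clinical summaries
#' (risk group, diagnosis), and the survival handoff (log-rank and Cox
#' hazard ratio CH-R vs CH-U).
#'
#' @param classes Tibble from [classify_ch()].
#' @param architecture Labeled architecture tibble.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @return A list with `sizes`, `dominant_composition`,
#'   `secondary_comparison`, `clinical_summary`, and `survival` (log-rank +
#'   Cox comparison of CH-R vs CH-U, `NULL` if either class is empty).
#' @export
ch_profile <- function(classes, architecture, clinical) {
  check_columns(classes, c("patient_id", "ch_class"), what = "classes")
  sizes <- classes |>
    count(.data$ch_class, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))

  lab <- left_join(architecture, classes, by = "patient_id")
  class_sizes <- count(classes, .data$ch_class, name = "class_n")
  dominant_composition <- lab |>
    filter(.data$label == "dominant") |>
    distinct(.data$patient_id, .data$gene, .data$ch_class) |>
    count(.data$ch_class, .data$gene, name = "n_patients") |>
    left_join(class_sizes, by = "ch_class") |>
    mutate(fraction = .data$n_patients / .data$class_n) |>
    select(-"class_n") |>
    arrange(.data$ch_class, desc(.data$n_patients))

  # secondary mutation frequencies, CH-R vs CH-U
  secondary_comparison <- NULL
  n_r <- sum(classes$ch_class == "CH_R")
  n_u <- sum(classes$ch_class == "CH_U")
  if (n_r > 0 && n_u > 0) {
    sec <- lab |>
      filter(.data$label == "secondary", .data$ch_class %in% c("CH_R", "CH_U")) |>
      distinct(.data$patient_id, .data$gene, .data$ch_class)
    genes <- unique(sec$gene)
    if (length(genes) > 0) {
      rows <- purrr::map(genes, function(g) {
        a <- sum(sec$gene == g & sec$ch_class == "CH_R")
        c_ <- sum(sec$gene == g & sec$ch_class == "CH_U")
        ft <- fisher_2x2(a, n_r - a, c_, n_u - c_)
        tibble(gene = g, freq_ch_r = a / n_r, freq_ch_u = c_ / n_u,
          odds_ratio = ft$odds_ratio, p = ft$p)
      })
      secondary_comparison <- bind_rows(rows) |>
        mutate(q = bh_adjust(.data$p), significant = .data$q < 0.01) |>
        arrange(.data$p)
    }
  }

  clin <- inner_join(classes, clinical, by = "patient_id")
  clinical_summary <- clin |>
    group_by(.data$ch_class) |>
    summarise(
      n = n(),
      low_risk_frac = mean(.data$risk_group == "low"),
      mds_frac = mean(.data$diagnosis == "MDS"),
      mds_mpn_frac = mean(.data$diagnosis == "MDS_MPN"),
      saml_frac = mean(.data$diagnosis == "sAML"),
      .groups = "drop"
    )

  surv <- NULL
  two <- filter(clin, .data$ch_class %in% c("CH_R", "CH_U"))
  if (length(unique(two$ch_class)) == 2 && sum(two$os_event) > 0) {
    surv <- list(
      logrank = logrank(two, group = "ch_class"),
      cox = cox_hr(two$ch_class == "CH_U", two$os_months, two$os_event)
    )
  }

  list(
    sizes = sizes,
    dominant_composition = dominant_composition,
    secondary_comparison = secondary_comparison,
    clinical_summary = clinical_summary,
    survival = surv
  )
}
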