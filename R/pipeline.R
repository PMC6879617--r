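#' Pipeline run configuration
#'
#' Assembles (and validates) everything [run_all()] needs: either paths to
#' the three cohort tables or a [sim_config()] to generate them, the
#' clustering configuration, the association thresholds, and the seed.
#' Referenced files must exist at validation time.
#'
#' @param mutations,seg,clinical Optional input file paths (TSV / SEG).
#' @param simulate Optional [sim_config()]; mutually exclusive with file
#'   inputs.
#' @param dp A [dp_config()].
#' @param min_depth,min_alt Variant filters.
#' @param min_dom_freq,min_sec_freq,q_co,q_ex Association thresholds.
#' @param vaf_cut VAF stratification threshold for survival analyses.
#' @param survival_gene Gene used for the rank survival comparison.
#' @param out_dir Output directory for [write_results()].
#' @param seed Master seed (propagated to simulation and clustering).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mutations = NULL, seg = NULL, clinical = NULL,
                       simulate = NULL, dp = dp_config(),
                       min_depth = 20, min_alt = 5,
                       min_dom_freq = 0.01, min_sec_freq = 0.01,
                       q_co = 0.01, q_ex = 0.25, vaf_cut = 0.4,
                       survival_gene = "TP53", out_dir = NULL,
                       seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(mutations) || is.null(clinical)) {
      stop_config("either file inputs (mutations + clinical) or a simulate config is required")
    }
    for (p in c(mutations, seg, clinical)) {
      if (!is.null(p) && !file.exists(p)) {
        stop_config(sprintf("input file does not exist: %s", p))
      }
    }
  } else if (!inherits(simulate, "sim_config")) {
    stop_config("simulate must be a sim_config object")
  }
  structure(list(
    mutations = mutations, seg = seg, clinical = clinical,
    simulate = simulate, dp = dp, min_depth = min_depth, min_alt = min_alt,
    min_dom_freq = min_dom_freq, min_sec_freq = min_sec_freq,
    q_co = q_co, q_ex = q_ex, vaf_cut = vaf_cut,
    survival_gene = survival_gene, out_dir = out_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config()] arguments
#' (nested `dp:` and `simulate:` blocks map onto [dp_config()] and
#' [sim_config()]).
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  dp <- do.call(dp_config, raw$dp %||% list())
  simulate <- if (!is.null(raw$simulate)) do.call(sim_config, raw$simulate)
  args <- raw[setdiff(names(raw), c("dp", "simulate"))]
  do.call(run_config, c(args, list(dp = dp, simulate = simulate)))
}

#' Run the full pipeline
#'
#' Executes the stages in order: simulate (or read inputs), variant
#' filtering, VAF-to-TCF adjustment, per-patient clustering and labeling,
#' pair association tables, lesion correlation, phenotype odds ratios,
#' HMA-response association, CH classification and profile, and the rank
#' survival comparison.  Any stage failure aborts with the failing stage
#' named.  When `out_dir` is set, result tables are written with a JSON
#' manifest; identical config and seed reproduce identical outputs.
#'
#' @param config A [run_config()] object.
#' @return A list with the stage results (`cohort`, `adjusted`,
#'   `architecture`, `pairs`, `lesions`, `phenotype`, `hma`, `ch`,
#'   `survival`, `manifest`).
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stop_config("config must come from run_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
        conditionMessage(e)), class = "clonehier_stage_error", parent = e)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      sc$seed <- config$seed
      sim <- simulate_cohort(sc)
      list(mutations = sim$mutations, clinical = sim$clinical,
        cn_segments = sim$cn_segments, sim = sim)
    } else {
      list(
        mutations = read_mutation_table(config$mutations),
        clinical = read_clinical(config$clinical),
        cn_segments = if (!is.null(config$seg)) read_seg(config$seg) else NULL,
        sim = NULL
      )
    }
  })

  filtered <- stage("filter", filter_variants(cohort$mutations,
    min_depth = config$min_depth, min_alt = config$min_alt))
  adjusted <- stage("adjust", adjust_vaf(filtered, cohort$cn_segments))
  dpc <- config$dp
  dpc$seed <- config$seed
  architecture <- stage("cluster", infer_architecture(adjusted, dpc))
  pairs <- stage("pairs", pair_tables(architecture,
    min_dom_freq = config$min_dom_freq, min_sec_freq = config$min_sec_freq,
    q_co = config$q_co, n_patients = nrow(cohort$clinical)))
  lesion_tbl <- stage("lesions", {
    les <- bind_rows(
      distinct(architecture, .data$patient_id, lesion = .data$gene),
      if (!is.null(cohort$cn_segments) && nrow(cohort$cn_segments) > 0) {
        cohort$cn_segments |>
          mutate(lesion = paste0(.data$region_class, "_chr", .data$chrom)) |>
          distinct(.data$patient_id, .data$lesion)
      }
    )
    lesion_correlation(les, n_patients = nrow(cohort$clinical),
      q_co = config$q_co, q_ex = config$q_ex)
  })
  phenotype <- stage("phenotype", list(
    mpn = phenotype_or(architecture, cohort$clinical,
      grouping = "single_lesion", phenotype = "mpn"),
    risk = phenotype_or(architecture, cohort$clinical,
      grouping = "single_lesion", phenotype = "risk")
  ))
  hma <- stage("hma", {
    if (any(cohort$clinical$hma_treated)) {
      hma_association(architecture, cohort$clinical)
    } else NULL
  })
  ch <- stage("chclass", {
    classes <- classify_ch(architecture,
      patient_ids = cohort$clinical$patient_id)
    list(classes = classes,
      profile = ch_profile(classes, architecture, cohort$clinical))
  })
  surv <- stage("outcomes", survival_by_rank(architecture, cohort$clinical,
    gene = config$survival_gene, vaf_cut = config$vaf_cut))

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- stage("write", write_results(
      list(
        architecture = as_tibble(architecture),
        pairs = pairs,
        lesions = lesion_tbl,
        phenotype_mpn = phenotype$mpn,
        phenotype_risk = phenotype$risk,
        ch_classes = ch$classes
      ),
      config$out_dir,
      config = config[setdiff(names(config), "out_dir")]
    ))
  }

  list(cohort = cohort, adjusted = adjusted, architecture = architecture,
    pairs = pairs, lesions = lesion_tbl, phenotype = phenotype, hma = hma,
    ch = ch, survival = surv, manifest = manifest)
}
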