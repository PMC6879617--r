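#' Consensus clustering of a posterior trace
#'
#' Builds the posterior co-assignment similarity matrix from the trace,
#' runs average-linkage hierarchical clustering on one minus the
#' similarity, and cuts the dendrogram at the number of clusters that
#' maximizes the posterior expected adjusted Rand criterion (PEAR) with
#' respect to the similarity matrix.  Clusters whose posterior mean
#' prevalence falls below the configured error-rate floor are merged into
#' their nearest neighbor in prevalence.
#'
#' @param fit A [fit_patient()] result.
#' @return A list with `assignment` (integer cluster per mutation, in the
#'   fit's canonical order), `clusters` (tibble `cluster, phi_mean, phi_sd,
#'   n_members`), and `psm` (the similarity matrix).
#' @export
consensus_clusters <- function(fit) {
  if (!inherits(fit, "dp_fit")) stop_validation("consensus_clusters() needs a dp_fit")
  if (nrow(fit$z) == 0) stop_validation("empty trace")
  n <- ncol(fit$z)
  if (n == 1) {
    assignment <- 1L
  } else {
    psm <- posterior_similarity(fit$z)
    hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
    best <- 1L
    best_pear <- -Inf
    for (k in seq_len(n)) {
      part <- stats::cutree(hc, k = k)
      val <- pear_criterion(part, psm)
      if (val > best_pear + 1e-12) {
        best_pear <- val
        best <- k
      }
    }
    assignment <- stats::cutree(hc, k = best)
  }
  if (n == 1) psm <- matrix(1, 1, 1)

  # posterior mean prevalence per consensus cluster: average the traced
  # per-mutation prevalences over samples and members
  stats_tbl <- purrr::map(sort(unique(assignment)), function(k) {
    members <- which(assignment == k)
    vals <- as.vector(fit$phi[, members, drop = FALSE])
    tibble(cluster = k, phi_mean = mean(vals), phi_sd = sd(vals),
      n_members = length(members))
  }) |> bind_rows()

  # prevalence floor: merge sub-error clusters into the nearest neighbor
  floor_ <- fit$config$error_rate
  while (nrow(stats_tbl) > 1 && any(stats_tbl$phi_mean < floor_)) {
    low <- which.min(stats_tbl$phi_mean)
    others <- setdiff(seq_len(nrow(stats_tbl)), low)
    nearest <- others[which.min(abs(stats_tbl$phi_mean[others] -
      stats_tbl$phi_mean[low]))]
    assignment[assignment == stats_tbl$cluster[low]] <-
      stats_tbl$cluster[nearest]
    keep <- sort(unique(assignment))
    assignment <- match(assignment, keep)
    stats_tbl <- purrr::map(sort(unique(assignment)), function(k) {
      members <- which(assignment == k)
      vals <- as.vector(fit$phi[, members, drop = FALSE])
      tibble(cluster = k, phi_mean = mean(vals), phi_sd = sd(vals),
        n_members = length(members))
    }) |> bind_rows()
  }

  list(assignment = assignment, clusters = stats_tbl, psm = psm)
}

# posterior co-assignment probability matrix from a trace of assignments
posterior_similarity <- function(z_trace) {
  n <- ncol(z_trace)
  psm <- matrix(0, n, n)
  for (t in seq_len(nrow(z_trace))) {
    zt <- z_trace[t, ]
    psm <- psm + outer(zt, zt, "==")
  }
  psm / nrow(z_trace)
}

# posterior expected adjusted Rand of a hard partition against a
# co-assignment probability matrix (Fritsch & Ickstadt criterion)
pear_criterion <- function(partition, psm) {
  n <- length(partition)
  ut <- upper.tri(psm)
  I <- outer(partition, partition, "==")[ut]
  P <- psm[ut]
  B <- sum(ut)
  sumI <- sum(I); sumP <- sum(P); sumIP <- sum(I * P)
  expected <- sumI * sumP / B
  denom <- 0.5 * (sumI + sumP) - expected
  if (abs(denom) < 1e-12) return(1)
  (sumIP - expected) / denom
}

#' Reduce consensus clusters to dominant/secondary labels
#'
#' The cluster with the highest posterior mean prevalence is the dominant
#' clone (ties broken by more members, then by the smallest canonical
#' mutation identifier); every other cluster's mutations are secondary.
#' With `largest_by = "members"` in the config, the most populous cluster
#' is dominant instead.  Mutations excluded from clustering are labeled by
#' their nearest cluster in TCF distance.
#'
#' @param consensus A [consensus_clusters()] result.
#' @param fit The corresponding [fit_patient()] object.
#' @param excluded Optional tibble of excluded mutations (needs `tcf`).
#' @return A tibble with one row per mutation: the fit's canonical columns
#'   plus `cluster`, `phi_mean`, `label` and `excluded`; attribute
#'   `phi_tied` records whether the dominant choice involved a prevalence
#'   tie (a potential co-dominant situation).
#' @export
label_dominant <- function(consensus, fit, excluded = NULL) {
  cl <- consensus$clusters
  if (nrow(cl) == 0) stop_validation("no clusters to label")
  assignment <- consensus$assignment
  mut <- fit$mutations

  key <- if (fit$config$largest_by == "members") {
    order(-cl$n_members, -cl$phi_mean)
  } else {
    # smallest canonical member id as final tie-break
    first_member <- vapply(cl$cluster, function(k) {
      min(which(assignment == k))
    }, integer(1))
    order(-round(cl$phi_mean, 10), -cl$n_members, first_member)
  }
  dominant_cluster <- cl$cluster[key[1]]
  phi_tied <- nrow(cl) > 1 &&
    sum(abs(cl$phi_mean - max(cl$phi_mean)) < 1e-10) > 1

  out <- mut |>
    mutate(
      cluster = assignment,
      phi_mean = cl$phi_mean[match(assignment, cl$cluster)],
      label = if_else(assignment == dominant_cluster, "dominant", "secondary"),
      excluded = FALSE
    )
  if (!is.null(excluded) && nrow(excluded) > 0) {
    check_columns(excluded, "tcf", what = "excluded mutations")
    nearest <- vapply(excluded$tcf, function(v) {
      which.min(abs(cl$phi_mean - v))
    }, integer(1))
    exc <- excluded |>
      mutate(
        cluster = cl$cluster[nearest],
        phi_mean = cl$phi_mean[nearest],
        label = if_else(.data$cluster == dominant_cluster,
          "dominant", "secondary"),
        excluded = TRUE
      )
    out <- bind_rows(out, exc)
  }
  attr(out, "phi_tied") <- phi_tied
  out
}

#' Infer per-patient clonal architecture for a cohort
#'
#' Runs the Dirichlet-process beta-binomial fit, consensus clustering and
#' dominant/secondary labeling for every patient of an adjusted mutation
#' table.  Indel/repetitive calls (`excluded = TRUE`) are withheld from the
#' sampler and labeled post hoc by nearest prevalence; patients whose
#' mutations are all excluded get a single cluster at their mean TCF.
#' Each patient's chain is seeded deterministically from the config seed
#' and the patient identifier, so results do not depend on patient or
#' mutation order.
#'
#' @param adjusted Adjusted mutation tibble ([adjust_vaf()]), with
#'   `patient_id` and optionally `excluded`.
#' @param config A [dp_config()] object.
#' @return An object of class `clonal_architecture`: a tibble with one row
#'   per mutation (`patient_id, mut_id, gene, chrom, pos, tcf, cluster,
#'   phi_mean, label, excluded`), with the per-patient fits stored in the
#'   `fits` attribute.
#' @export
infer_architecture <- function(adjusted, config = dp_config()) {
  check_columns(adjusted, c("patient_id", "tcf", "branch_used"),
    what = "adjusted mutations")
  if (!"excluded" %in% names(adjusted)) adjusted$excluded <- FALSE
  patients <- sort(unique(adjusted$patient_id))
  fits <- list()
  rows <- purrr::map(patients, function(p) {
    pm <- filter(adjusted, .data$patient_id == p)
    clustered <- filter(pm, !.data$excluded)
    excl <- filter(pm, .data$excluded)
    if (nrow(clustered) == 0) {
      # nothing to cluster: one pseudo-clone at the mean TCF, all dominant
      return(mutate(excl,
        cluster = 1L, phi_mean = mean(excl$tcf),
        label = "dominant", excluded = TRUE))
    }
    pcfg <- config
    pcfg$seed <- derive_seed(config$seed, id_hash(p))
    fit <- fit_patient(clustered, pcfg)
    cons <- consensus_clusters(fit)
    label_dominant(cons, fit, excluded = excl)
  })
  out <- bind_rows(rows)
  class(out) <- c("clonal_architecture", class(out))
  out
}

# deterministic small hash of a patient identifier
id_hash <- function(x) {
  sum(utf8ToInt(as.character(x)) * seq_along(utf8ToInt(as.character(x))))
}

#' Cohort-level summary of clonal architectures
#'
#' Clone-count histogram over patients, per-gene dominant/secondary counts
#' and fractions, and the comparison of adjusted VAF (TCF) distributions
#' between dominant and secondary mutations by Wilcoxon rank-sum test.
#'
#' @param architecture A [infer_architecture()] result (or any tibble with
#'   `patient_id, gene, cluster, label, tcf`).
#' @return A list with `clone_histogram`, `gene_ranks`, and
#'   `vaf_comparison` (medians and rank-sum p; `NULL` if either rank is
#'   absent).
#' @export
cohort_summary <- function(architecture) {
  check_columns(architecture, c("patient_id", "gene", "cluster", "label", "tcf"),
    what = "architecture")
  if (nrow(architecture) == 0) stop_validation("empty architecture")
  clone_histogram <- architecture |>
    group_by(.data$patient_id) |>
    summarise(n_clones = dplyr::n_distinct(.data$cluster), .groups = "drop") |>
    count(.data$n_clones, name = "n_patients") |>
    mutate(fraction = .data$n_patients / sum(.data$n_patients))

  gene_ranks <- architecture |>
    count(.data$gene, .data$label, name = "n") |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
      values_fill = 0L)
  if (!"dominant" %in% names(gene_ranks)) gene_ranks$dominant <- 0L
  if (!"secondary" %in% names(gene_ranks)) gene_ranks$secondary <- 0L
  gene_ranks <- gene_ranks |>
    mutate(dominant_fraction =
      .data$dominant / pmax(1L, .data$dominant + .data$secondary))

  vaf_comparison <- NULL
  dom <- architecture$tcf[architecture$label == "dominant"]
  sec <- architecture$tcf[architecture$label == "secondary"]
  if (length(dom) > 0 && length(sec) > 0) {
    wt <- suppressWarnings(wilcox.test(dom, sec))
    vaf_comparison <- tibble(
      median_dominant = median(dom),
      median_secondary = median(sec),
      p_ranksum = wt$p.value
    )
  }
  list(clone_histogram = clone_histogram, gene_ranks = gene_ranks,
    vaf_comparison = vaf_comparison)
}

#' Tidy a Dirichlet-process fit
#'
#' One row per mutation with its consensus cluster, posterior mean
#' prevalence of the mutation's traced prevalence, and posterior standard
#' deviation.
#'
#' @param x A `dp_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dp_fit <- function(x, ...) {
  cons <- consensus_clusters(x)
  tibble(
    mut_id = x$mutations$mut_id %||% sprintf("m%03d", seq_len(ncol(x$z))),
    gene = x$mutations$gene %||% NA_character_,
    cluster = cons$assignment,
    phi_mean = colMeans(x$phi),
    phi_sd = apply(x$phi, 2, sd)
  )
}

#' Glance at a Dirichlet-process fit
#'
#' @param x A `dp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: number of mutations, consensus clone count,
#'   posterior mean precision, kept samples.
#' @export
glance.dp_fit <- function(x, ...) {
  cons <- consensus_clusters(x)
  tibble(
    n_mutations = ncol(x$z),
    n_clones = nrow(cons$clusters),
    precision_mean = mean(x$s),
    n_samples = nrow(x$z)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
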