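#' Plot Kaplan-Meier curves
#'
#' Step curves for one or several [km_estimate()] fits.
#'
#' @param km Named list of `km_fit` objects (or a single fit).
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  if (inherits(km, "km_fit")) km <- list(all = km)
  dat <- purrr::imap(km, function(fit, name) {
    bind_rows(
      tibble(time = 0, surv = 1),
      select(fit$curve, "time", "surv")
    ) |> mutate(group = name)
  }) |> bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
    color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival",
      color = NULL) +
    ggplot2::theme_minimal()
}

#' Bubble plot of dominant/secondary pair associations
#'
#' Pairs on a dominant-by-secondary grid; circle size encodes significance
#' (-log10 q) and color the direction (co-occurrence vs mutual
#' exclusivity).
#'
#' @param pairs A [pair_tables()] result.
#' @param q_max Only pairs with `q` below this are drawn (default 0.25).
#' @return A ggplot object.
#' @export
plot_pair_bubbles <- function(pairs, q_max = 0.25) {
  dat <- filter(pairs, .data$q < q_max)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$secondary, y = .data$dominant,
    size = -log10(pmax(.data$q, 1e-30)), color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(
      co_occurrence = "#7b3294", mutual_exclusivity = "#008837")) +
    ggplot2::labs(x = "Secondary mutation", y = "Dominant mutation",
      size = "-log10 q", color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a patient's clonal architecture
#'
#' Adjusted VAF (TCF) per mutation, colored by consensus cluster and
#' shaped by dominant/secondary label.
#'
#' @param object A `clonal_architecture` tibble (from
#'   [infer_architecture()]).
#' @param patient Patient identifier to plot (default: first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clonal_architecture <- function(object, patient = NULL, ...) {
  if (is.null(patient)) patient <- object$patient_id[1]
  dat <- filter(object, .data$patient_id == !!patient) |>
    arrange(desc(.data$tcf)) |>
    mutate(gene = factor(.data$gene, levels = unique(.data$gene)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$tcf,
    color = factor(.data$cluster), shape = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$phi_mean,
      color = factor(.data$cluster)), linetype = "dashed", alpha = 0.4) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = patient, x = NULL, y = "Tumor cell fraction",
      color = "Clone", shape = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
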