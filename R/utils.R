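# internal validation helpers; all user-facing errors are classed so callers
# and tests can distinguish schema vs validation vs config failures.

stop_schema <- function(msg, ...) {
  abort(msg, class = "clonehier_schema_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "clonehier_validation_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "clonehier_config_error", ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = "clonehier_io_error", ...)
}

# check that `df` has all `cols`; name the first missing column.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# deterministic seed derivation for per-unit streams; keeps values < 2^31.
derive_seed <- function(seed, index) {
  (as.integer(seed) + 104729L * (as.integer(index) %% 20011L)) %% 2147483629L
}

#' Path to a packaged reference table
#'
#' Convenience accessor for the plain-text tables shipped with the package
#' (the 36-gene panel defaults and the published dominant/secondary pair
#' counts used in regression tests).
#'
#' @param file File name under `extdata/`, e.g. `"gene_panel.tsv"` or
#'   `"table2_counts.tsv"`.
#' @return Absolute path to the packaged file.
#' @export
clonehier_extdata <- function(file) {
  path <- system.file("extdata", file, package = "clonehier")
  if (!nzchar(path)) stop_io(sprintf("packaged file not found: %s", file))
  path
}

#' Published dominant/secondary pair counts
#'
#' Loads the packaged 37-row table of significantly associated dominant to
#' secondary mutation pairs from a 1809-patient MDS cohort: 2x2 cell counts
#' (co-occurrence / dominant only / secondary only / intact), the printed
#' odds ratio, p-value, q-value and direction (CO = co-occurrence,
#' ME = mutual exclusivity).
#'
#' @return A tibble with one row per pair.
#' @export
pair_counts_reference <- function() {
  readr::read_tsv(
    clonehier_extdata("table2_counts.tsv"),
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      dominant = "c", secondary = "c",
      co_occurrence = "i", dominant_only = "i",
      secondary_only = "i", intact = "i",
      or_printed = "c", p_printed = "d", q_printed = "d", direction = "c"
    )
  )
}

#' Default 36-gene myeloid panel
#'
#' Loads the packaged synthetic gene panel used by the cohort generator:
#' gene symbol, approximate chromosome, a synthetic point coordinate, the
#' marginal per-patient mutation frequency emulated by the simulator, and
#' the expected fraction of the gene's mutations that are dominant.
#'
#' @return A tibble with one row per gene.
#' @export
gene_panel_default <- function() {
  readr::read_tsv(
    clonehier_extdata("gene_panel.tsv"),
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      gene = "c", chrom = "c", pos = "d", freq = "d", dominant_share = "d"
    )
  )
}
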