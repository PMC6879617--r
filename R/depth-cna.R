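#' Standardize an exon depth matrix
#'
#' Per sample, the standardized depth of each exon is its raw summed depth
#' rescaled so the sample's standardized depths sum to a fixed constant
#' `k0` (default 1).  Standardization is invariant to per-sample scaling of
#' raw depths and idempotent.
#'
#' @param depth A tibble with exon metadata columns (`chrom, start, end,
#'   exon_id`) followed by one numeric column per sample, or a plain
#'   numeric matrix (exons x samples).
#' @param k0 Target sum per sample.
#' @return The same structure with sample columns standardized.
#' @export
standardize_depth <- function(depth, k0 = 1) {
  dm <- as_depth_matrix(depth)
  sums <- colSums(dm$mat)
  zero <- sums <= 0
  if (any(zero)) {
    stop_validation(sprintf("sample(s) with all-zero depth: %s",
      paste(colnames(dm$mat)[zero], collapse = ", ")))
  }
  if (any(dm$mat < 0)) stop_validation("depths must be non-negative")
  std <- sweep(dm$mat, 2, sums / k0, "/")
  rebuild_depth(dm, std)
}

as_depth_matrix <- function(depth) {
  meta_cols <- intersect(c("chrom", "start", "end", "exon_id"), names(depth))
  if (is.matrix(depth)) {
    return(list(meta = NULL, mat = depth))
  }
  mat <- as.matrix(depth[setdiff(names(depth), meta_cols)])
  storage.mode(mat) <- "double"
  list(meta = depth[meta_cols], mat = mat)
}

rebuild_depth <- function(dm, mat) {
  if (is.null(dm$meta)) return(mat)
  bind_cols(dm$meta, as_tibble(mat))
}

#' Select a panel of best-correlated normals
#'
#' Ranks normal samples by Pearson correlation of standardized exon depths
#' with the query sample and returns the identifiers of the top `m0`
#' (default 12); ties are broken deterministically by identifier order.
#'
#' @param sample_vec Standardized depth vector of the query sample.
#' @param normals Matrix (exons x normals) or tibble of standardized
#'   normal depths with sample columns.
#' @param m0 Panel size.
#' @return Character vector of the `m0` selected identifiers, in
#'   decreasing correlation order.
#' @export
select_panel <- function(sample_vec, normals, m0 = 12) {
  nm <- as_depth_matrix(normals)$mat
  if (ncol(nm) < m0) {
    stop_validation(sprintf("need at least m0 = %d normals, got %d",
      m0, ncol(nm)))
  }
  r <- as.vector(cor(sample_vec, nm))
  ids <- colnames(nm)
  ord <- order(-r, ids)
  ids[ord][seq_len(m0)]
}

#' Per-exon copy ratio against a panel of normals
#'
#' The copy ratio of each exon is the sample's standardized depth divided
#' by the mean standardized depth of the panel samples.  Only exons whose
#' raw mean depth across the cohort exceeds `min_mean_depth` (strict,
#' default 500) are evaluated; exons where the panel mean is zero are
#' returned as `NA` (flagged missing, not an error).
#'
#' @param sample_vec Standardized depth vector of the query sample.
#' @param panel Matrix/tibble of standardized depths of the panel samples.
#' @param raw_means Per-exon mean raw depth across samples (for the depth
#'   filter); `NULL` disables the filter.
#' @param min_mean_depth Strict lower bound on `raw_means`.
#' @return Numeric vector of copy ratios, `NA` where filtered or
#'   undefined.
#' @export
copy_ratio <- function(sample_vec, panel, raw_means = NULL,
                       min_mean_depth = 500) {
  pm <- as_depth_matrix(panel)$mat
  if (ncol(pm) == 0) stop_validation("panel must be nonempty")
  ref <- rowMeans(pm)
  cn <- rep(NA_real_, length(sample_vec))
  pass <- if (is.null(raw_means)) rep(TRUE, length(sample_vec)) else
    raw_means > min_mean_depth
  ok <- pass & ref > 0
  cn[ok] <- sample_vec[ok] / ref[ok]
  cn
}

#' Segment a copy-ratio profile by circular binary segmentation
#'
#' Splits the genome-ordered per-exon copy ratios into segments by
#' recursive circular binary segmentation (permutation-tested maximal
#' two-segment statistic) and assigns each exon its segment mean.  The
#' profile is treated as circularly closed: the first significant split
#' separates an arc from its wrapped complement, which remains a single
#' segment (so a focal lesion does not fragment the flanking neutral
#' sequence); both arcs are refined recursively.  `NA` exons are carried
#' through unchanged and do not enter the segmentation.
#'
#' @param cn Numeric vector of copy ratios in genome order (`NA` allowed).
#' @param alpha Permutation significance level for accepting a split.
#' @param nperm Number of within-segment permutations.
#' @param min_width Minimum segment width in exons.
#' @param seed Optional integer seed making the permutation p-values
#'   deterministic.
#' @return A tibble `exon` (input position), `cn`, `segment`, `seg_mean`.
#' @export
segment_ratio <- function(cn, alpha = 0.01, nperm = 1000, min_width = 2,
                          seed = NULL) {
  if (length(cn) < 1) stop_validation("segment_ratio needs at least one exon")
  if (!is.null(seed)) set.seed(seed)
  obs <- which(!is.na(cn))
  out <- tibble(exon = seq_along(cn), cn = cn,
    segment = NA_integer_, seg_mean = NA_real_)
  if (length(obs) == 0) return(out)
  x <- cn[obs]
  seg_of <- cbs_assign(x, alpha = alpha, nperm = nperm,
    min_width = min_width)
  means <- tapply(x, seg_of, mean)
  out$segment[obs] <- as.integer(seg_of)
  out$seg_mean[obs] <- as.numeric(means[as.character(seg_of)])
  out
}

#' Call copy-number lesions from segmented profiles
#'
#' For each exon, the mean and standard deviation of the segmented copy
#' ratio are computed across all cohort samples; a sample's exon is called
#' a loss when its segmented value falls strictly below mean - 4 SD and a
#' gain when strictly above mean + 4 SD (values exactly at the boundary
#' are neutral).  Exons with zero dispersion are neutral unless a value
#' differs from the mean, in which case the call is flagged `degenerate`.
#'
#' @param segmented Matrix (exons x samples) of segmented copy ratios, or
#'   a tibble with sample columns.
#' @param n_sd Number of standard deviations (default 4).
#' @param trim Fraction trimmed from each tail when estimating the SD
#'   (default 0, i.e. the plain SD; a small trim guards against outlier
#'   inflation).
#' @return A tibble `exon, sample, value, exon_mean, exon_sd, call`
#'   (`loss`, `neutral`, `gain`, `degenerate`).
#' @export
call_lesions <- function(segmented, n_sd = 4, trim = 0) {
  sm <- as_depth_matrix(segmented)$mat
  if (ncol(sm) < 3) stop_validation("need at least 3 samples to estimate the SD")
  trimmed_sd <- function(v) {
    v <- v[!is.na(v)]
    if (trim > 0 && length(v) > 4) {
      qs <- quantile(v, c(trim, 1 - trim), names = FALSE)
      v <- v[v >= qs[1] & v <= qs[2]]
    }
    sd(v)
  }
  E <- rowMeans(sm, na.rm = TRUE)
  SD <- apply(sm, 1, trimmed_sd)
  out <- purrr::map(seq_len(ncol(sm)), function(j) {
    v <- sm[, j]
    call <- rep("neutral", length(v))
    zero_sd <- !is.na(SD) & SD == 0
    call[!zero_sd & !is.na(v) & v < E - n_sd * SD] <- "loss"
    call[!zero_sd & !is.na(v) & v > E + n_sd * SD] <- "gain"
    call[zero_sd & !is.na(v) & v != E] <- "degenerate"
    call[is.na(v)] <- NA_character_
    tibble(exon = seq_along(v), sample = colnames(sm)[j] %||%
        as.character(j), value = v, exon_mean = E, exon_sd = SD,
      call = call)
  })
  bind_rows(out)
}

#' Digital copy-number pipeline for a depth matrix
#'
#' End-to-end: standardizes the depth matrix, selects a per-sample panel
#' of best-correlated normals, computes copy ratios on exons passing the
#' mean-depth filter, segments each profile by circular binary
#' segmentation, and calls losses/gains at the 4-SD rule across all
#' processed samples.  Calls translate to copy-number states as loss =
#' deletion (tcn 1, ascn 0) and gain (tcn 3, ascn 1); copy-neutral LOH
#' cannot be detected from depth alone.
#'
#' @param depth Depth tibble (`chrom, start, end, exon_id` + sample
#'   columns) of raw per-exon summed depths.
#' @param normal_ids Identifiers of the reference normal samples.
#' @param sample_ids Samples to profile (default: all samples).
#' @param m0 Panel size per sample.
#' @param min_mean_depth Strict exon mean-depth filter.
#' @param alpha,nperm,min_width Segmentation parameters ([segment_ratio()]).
#' @param n_sd,trim Calling parameters ([call_lesions()]).
#' @param center `"median"` (default) re-centers each sample's copy-ratio
#'   profile at its median before segmentation, so the neutral level sits
#'   at 1 regardless of the sample's lesion load (standardizing to a fixed
#'   total depth shifts all of a lesion-bearing sample's neutral exons
#'   otherwise); `"none"` disables.
#' @param seed Seed for the permutation p-values.
#' @return A list with `calls` (per exon and sample), `segments` (SEG-style
#'   tibble of non-neutral runs: `sample, chrom, start, end, region_class,
#'   tcn, ascn`), and `profiles` (per-sample segmented ratios).
#' @export
run_depth_cna <- function(depth, normal_ids, sample_ids = NULL, m0 = 12,
                          min_mean_depth = 500, alpha = 0.01, nperm = 1000,
                          min_width = 2, n_sd = 4, trim = 0,
                          center = c("median", "none"), seed = 1L) {
  center <- match.arg(center)
  dm <- as_depth_matrix(depth)
  all_ids <- colnames(dm$mat)
  if (!all(normal_ids %in% all_ids)) stop_validation("unknown normal sample id")
  if (is.null(sample_ids)) sample_ids <- all_ids
  raw_means <- rowMeans(dm$mat)
  std <- as_depth_matrix(standardize_depth(depth))$mat

  seg_mat <- matrix(NA_real_, nrow(std), length(sample_ids),
    dimnames = list(NULL, sample_ids))
  for (sid in sample_ids) {
    pool <- setdiff(normal_ids, sid)
    panel_ids <- select_panel(std[, sid], std[, pool, drop = FALSE],
      m0 = min(m0, length(pool)))
    cn <- copy_ratio(std[, sid], std[, panel_ids, drop = FALSE],
      raw_means = raw_means, min_mean_depth = min_mean_depth)
    if (center == "median" && any(!is.na(cn))) {
      cn <- cn / median(cn, na.rm = TRUE)
    }
    seg <- segment_ratio(cn, alpha = alpha, nperm = nperm,
      min_width = min_width, seed = derive_seed(seed, id_hash(sid)))
    seg_mat[, sid] <- seg$seg_mean
  }
  calls <- call_lesions(seg_mat, n_sd = n_sd, trim = trim)

  segments <- NULL
  if (!is.null(dm$meta) && all(c("chrom", "start", "end") %in% names(dm$meta))) {
    segments <- calls |>
      filter(.data$call %in% c("loss", "gain")) |>
      mutate(
        chrom = dm$meta$chrom[.data$exon],
        start = dm$meta$start[.data$exon],
        end = dm$meta$end[.data$exon],
        region_class = if_else(.data$call == "loss", "deletion", "gain"),
        tcn = if_else(.data$call == "loss", 1, 3),
        ascn = if_else(.data$call == "loss", 0, 1)
      ) |>
      collapse_adjacent_calls()
  }
  list(calls = calls, segments = segments, profiles = seg_mat)
}

# merge runs of identically called adjacent exons into segments
collapse_adjacent_calls <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(sample = character(), chrom = character(),
      start = numeric(), end = numeric(), region_class = character(),
      tcn = numeric(), ascn = numeric()))
  }
  calls |>
    arrange(.data$sample, .data$chrom, .data$start) |>
    group_by(.data$sample, .data$chrom, .data$region_class) |>
    mutate(run = cumsum(c(1, diff(.data$exon) != 1))) |>
    group_by(.data$sample, .data$chrom, .data$region_class, .data$run) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      tcn = .data$tcn[1], ascn = .data$ascn[1], .groups = "drop"
    ) |>
    select("sample", "chrom", "start", "end", "region_class", "tcn", "ascn")
}
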