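#' Read a somatic mutation table
#'
#' Reads per-patient somatic mutation calls from a tab-separated table
#' (MAF-lite columns) or a single-sample VCF with `AD` and `DP` fields.
#' The observed variant allele frequency is always recomputed from read
#' counts (`alt_reads / depth`): counts are the primitive consumed by the
#' downstream clustering, so they win over any VAF column in the input.
#'
#' Required TSV columns: `patient_id, gene, variant_class, chrom, pos, ref,
#' alt, alt_reads, depth, bidirectional`.  Gene symbols are upper-cased;
#' genes outside the default panel are kept.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A tibble of mutation calls with one row per variant and columns
#'   `patient_id, gene, variant_class, chrom, pos, ref, alt, alt_reads,
#'   depth, vaf_obs, bidirectional` (plus `excluded` if present in the
#'   input, marking indel/repetitive-region calls withheld from clustering).
#' @export
read_mutation_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (format == "vcf") {
    return(read_mutation_vcf(path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "patient_id", "gene", "variant_class", "chrom", "pos", "ref", "alt",
    "alt_reads", "depth", "bidirectional"
  )
  check_columns(raw, required, what = "mutation table")
  calls <- raw |>
    mutate(
      patient_id = as.character(.data$patient_id),
      gene = toupper(as.character(.data$gene)),
      variant_class = as.character(.data$variant_class),
      chrom = as.character(.data$chrom),
      pos = as.numeric(.data$pos),
      alt_reads = as.integer(.data$alt_reads),
      depth = as.integer(.data$depth),
      bidirectional = as.logical(.data$bidirectional)
    )
  if (!"excluded" %in% names(calls)) calls$excluded <- FALSE
  calls <- calls |>
    mutate(vaf_obs = ifelse(.data$depth > 0, .data$alt_reads / .data$depth, NA_real_)) |>
    select(
      "patient_id", "gene", "variant_class", "chrom", "pos", "ref", "alt",
      "alt_reads", "depth", "vaf_obs", "bidirectional", "excluded"
    )
  validate_mutation_calls(calls)
  calls
}

read_mutation_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("VCF ingestion requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop_schema("VCF has no sample column")
  if (ncol(v@gt) > 2) stop_validation("VCF ingestion is restricted to single-sample records")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  if (all(is.na(ad))) stop_schema("VCF is missing the AD format field")
  if (all(is.na(dp))) stop_schema("VCF is missing the DP format field")
  alt_reads <- as.integer(vapply(
    strsplit(ad[, 1], ","), function(x) x[2], character(1)
  ))
  fix <- v@fix # matrix: CHROM POS ID REF ALT QUAL FILTER INFO
  gene <- rep(NA_character_, nrow(fix))
  info_gene <- unname(vcfR::extract.info(v, element = "GENE"))
  if (!all(is.na(info_gene))) gene <- toupper(info_gene)
  calls <- tibble(
    patient_id = colnames(v@gt)[2],
    gene = gene,
    variant_class = "other",
    chrom = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    alt_reads = alt_reads,
    depth = as.integer(dp[, 1]),
    bidirectional = TRUE,
    excluded = FALSE
  ) |>
    mutate(vaf_obs = .data$alt_reads / .data$depth) |>
    select(
      "patient_id", "gene", "variant_class", "chrom", "pos", "ref", "alt",
      "alt_reads", "depth", "vaf_obs", "bidirectional", "excluded"
    )
  validate_mutation_calls(calls)
  calls
}

validate_mutation_calls <- function(calls) {
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(calls$alt_reads < 0 | calls$depth < 0, na.rm = TRUE)) {
    stop_validation("negative read counts in mutation table")
  }
  if (any(calls$depth <= 0, na.rm = TRUE)) {
    stop_validation("depth must be a positive count")
  }
  bad <- which(calls$alt_reads > calls$depth)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "alt_reads exceeds depth for %d call(s) (first at row %d)",
      length(bad), bad[1]
    ))
  }
  invisible(calls)
}

#' Read copy-number segments (SEG format)
#'
#' Columns: `sample, chrom, start, end, region_class, tcn, ascn`.
#' Coordinates are 1-based inclusive.  `region_class` is one of
#' `neutral`, `deletion`, `gain`, `UPD`.
#'
#' @param path Path to the SEG file.
#' @return A tibble of segments with `patient_id` (renamed from `sample`).
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, c("sample", "chrom", "start", "end", "region_class", "tcn", "ascn"),
    what = "SEG file")
  seg <- raw |>
    mutate(
      patient_id = as.character(.data$sample),
      chrom = as.character(.data$chrom),
      start = as.numeric(.data$start),
      end = as.numeric(.data$end),
      region_class = as.character(.data$region_class),
      tcn = as.numeric(.data$tcn),
      ascn = as.numeric(.data$ascn)
    ) |>
    select("patient_id", "chrom", "start", "end", "region_class", "tcn", "ascn")
  validate_cn_segments(seg)
  seg
}

validate_cn_segments <- function(seg) {
  if (nrow(seg) == 0) return(invisible(seg))
  ok_class <- seg$region_class %in% c("neutral", "deletion", "gain", "UPD")
  if (!all(ok_class)) {
    stop_validation(sprintf(
      "unknown region_class: %s",
      paste(unique(seg$region_class[!ok_class]), collapse = ", ")
    ))
  }
  if (any(seg$region_class == "neutral" & seg$tcn != 2)) {
    stop_validation("neutral segments must have tcn = 2")
  }
  if (any(seg$region_class == "deletion" & seg$tcn >= 2)) {
    stop_validation("deletion segments must have tcn < 2")
  }
  if (any(seg$region_class == "UPD" & seg$tcn != 2)) {
    stop_validation("UPD segments must have tcn = 2")
  }
  if (any(seg$region_class == "gain" & seg$tcn != 3)) {
    stop_validation("gain segments use the tcn = 3 convention")
  }
  if (any(seg$ascn < 0 | seg$ascn > 1)) {
    stop_validation("ascn must lie in [0, 1]")
  }
  invisible(seg)
}

#' Read a clinical annotation table
#'
#' Columns: `patient_id, diagnosis, ipssr_score, os_months, os_event,
#' hma_treated, hma_response`.  The dichotomous risk group is derived from
#' the IPSS-R score (low if score <= 3.5, high otherwise).  `hma_response`
#' must be `NA` for untreated patients and one of `CR, PR, HI, none` for
#' treated ones.
#'
#' @param path Path to the clinical TSV.
#' @return A tibble with a derived `risk_group` column.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
    na = c("", "NA"))
  check_columns(raw, c(
    "patient_id", "diagnosis", "ipssr_score", "os_months", "os_event",
    "hma_treated", "hma_response"
  ), what = "clinical table")
  clin <- raw |>
    mutate(
      patient_id = as.character(.data$patient_id),
      diagnosis = as.character(.data$diagnosis),
      ipssr_score = as.numeric(.data$ipssr_score),
      os_months = as.numeric(.data$os_months),
      os_event = as.logical(.data$os_event),
      hma_treated = as.logical(.data$hma_treated),
      hma_response = as.character(.data$hma_response)
    )
  if ("antecedent" %in% names(raw)) {
    clin$antecedent <- as.character(raw$antecedent)
  }
  clin <- derive_risk_group(clin)
  validate_clinical(clin)
  clin
}

derive_risk_group <- function(clin) {
  mutate(clin, risk_group = if_else(.data$ipssr_score <= 3.5, "low", "high"))
}

validate_clinical <- function(clin) {
  if (nrow(clin) == 0) return(invisible(clin))
  if (!all(clin$diagnosis %in% c("MDS", "MDS_MPN", "sAML"))) {
    stop_validation("diagnosis must be one of MDS, MDS_MPN, sAML")
  }
  if (any(clin$ipssr_score < 0, na.rm = TRUE)) {
    stop_validation("ipssr_score must be non-negative")
  }
  if (any(clin$os_months < 0, na.rm = TRUE)) {
    stop_validation("os_months must be non-negative")
  }
  resp <- clin$hma_response
  bad_resp <- !is.na(resp) & !resp %in% c("CR", "PR", "HI", "none")
  if (any(bad_resp)) {
    stop_validation("hma_response must be CR, PR, HI, none or NA")
  }
  if (any(!is.na(resp) & !clin$hma_treated)) {
    stop_validation("hma_response present for an untreated patient")
  }
  invisible(clin)
}

#' Apply the cohort's variant-level filters
#'
#' Retains calls with sequencing depth of at least `min_depth`, at least
#' `min_alt` variant-supporting reads, and bidirectional read support.
#' Synonymous variants never enter the call table (enforced at read time),
#' so the three retained filters fully reproduce the variant-screening
#' rules.  Filtering is idempotent.
#'
#' @param calls Tibble of mutation calls (see [read_mutation_table()]).
#' @param min_depth Minimum total depth (default 20, boundary inclusive).
#' @param min_alt Minimum variant-supporting reads (default 5, inclusive).
#' @return The filtered tibble (possibly empty).
#' @export
filter_variants <- function(calls, min_depth = 20, min_alt = 5) {
  check_columns(calls, c("alt_reads", "depth", "bidirectional"),
    what = "mutation calls")
  filter(
    calls,
    .data$depth >= min_depth,
    .data$alt_reads >= min_alt,
    .data$bidirectional
  )
}

#' Attach overlapping copy-number state to mutation calls
#'
#' Matches each mutation to the copy-number segment of the same patient
#' containing its position (1-based inclusive interval).  Mutations with no
#' overlapping segment receive the neutral default (tcn 2, ascn 1).
#'
#' @param calls Mutation call tibble.
#' @param segments Copy-number segment tibble (see [read_seg()]); may be
#'   `NULL`, in which case every call is neutral.
#' @return `calls` with `region_class`, `tcn`, `ascn` columns appended.
#' @export
match_cn_state <- function(calls, segments = NULL) {
  out <- mutate(calls,
    region_class = "neutral", tcn = 2, ascn = 1
  )
  if (is.null(segments) || nrow(segments) == 0) return(out)
  validate_cn_segments(segments)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    hit <- out$patient_id == s$patient_id &
      out$chrom == s$chrom &
      out$pos >= s$start & out$pos <= s$end
    if (any(hit)) {
      out$region_class[hit] <- s$region_class
      out$tcn[hit] <- s$tcn
      out$ascn[hit] <- s$ascn
    }
  }
  out
}

#' Write result tables with a manifest
#'
#' Writes each named table as a TSV with stable column order and a JSON
#' manifest recording file names, row counts and a content hash of the
#' configuration used.  Re-running with identical inputs produces
#' byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if missing).
#' @param config Optional list; hashed into the manifest for provenance.
#' @return A tibble manifest (file, rows) invisibly; the JSON manifest is
#'   written as `manifest.json` in `out_dir`.
#' @export
write_results <- function(tables, out_dir, config = list()) {
  stopifnot(is.list(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory: %s", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop_io(sprintf("output directory not writable: %s", out_dir))
  }
  entries <- purrr::imap(tables, function(tbl, name) {
    file <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as_tibble(tbl), file, progress = FALSE)
    tibble(file = basename(file), rows = nrow(tbl))
  })
  manifest <- if (length(entries) > 0) bind_rows(entries) else
    tibble(file = character(), rows = integer())
  config_hash <- digest_config(config)
  jsonlite::write_json(
    list(
      files = manifest,
      config_hash = config_hash
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

# small stable hash of a config list (sum of serialized bytes; provenance
# marker only, not cryptographic)
digest_config <- function(config) {
  raw <- serialize(config, connection = NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% 4294967291)
}
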