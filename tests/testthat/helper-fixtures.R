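# fixtures built in code; no binary files

# a minimal valid mutation TSV
write_mutation_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("patient_id", "gene", "variant_class", "chrom", "pos",
    "ref", "alt", "alt_reads", "depth", "bidirectional"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

# two-clone patient at known prevalences; neutral copy number
make_two_clone_patient <- function(phis = c(0.8, 0.3), per_clone = 5,
                                   depth_range = c(500, 1000),
                                   patient = "P1", seed = 1) {
  set.seed(seed)
  n <- length(phis) * per_clone
  depth <- sample(depth_range[1]:depth_range[2], n, replace = TRUE)
  phi <- rep(phis, each = per_clone)
  alt_ct <- rbinom(n, depth, phi / 2)
  tibble::tibble(
    patient_id = patient,
    mut_id = sprintf("%s:m%02d", patient, seq_len(n)),
    gene = sprintf("G%02d", seq_len(n)),
    variant_class = "missense",
    chrom = "1", pos = seq_len(n) * 100,
    ref = "A", alt = "T",
    alt_reads = alt_ct, depth = depth,
    vaf_obs = alt_ct / depth,
    bidirectional = TRUE, excluded = FALSE,
    true_label = ifelse(phi == max(phis), "dominant", "secondary"),
    true_phi = phi
  )
}

# synthetic exon depth cohort with one tumor carrying a heterozygous
# deletion (0.5x depth) on the given exons; multiplicative noise CV 5%
make_deletion_depth <- function(n_exons = 120, n_normals = 40,
                                del_exons = 51:58, cv = 0.05, seed = 1) {
  set.seed(seed)
  base <- runif(n_exons, 600, 1200)
  draw <- function(scale = rep(1, n_exons)) {
    rpois(n_exons, base * scale * rnorm(n_exons, 1, cv))
  }
  normals <- sapply(seq_len(n_normals), function(i) draw())
  colnames(normals) <- sprintf("N%02d", seq_len(n_normals))
  scale <- rep(1, n_exons)
  scale[del_exons] <- 0.5
  tumor <- draw(scale)
  dplyr::bind_cols(
    tibble::tibble(chrom = "1", start = seq_len(n_exons) * 1000,
      end = seq_len(n_exons) * 1000 + 500,
      exon_id = sprintf("e%03d", seq_len(n_exons))),
    tibble::as_tibble(cbind(T1 = tumor, normals))
  )
}

# architecture + clinical pair for association/survival tests, built
# directly (no MCMC): each patient gets one dominant gene and possibly
# secondary genes
make_labeled_cohort <- function(n = 400, genes = sprintf("G%d", 1:8),
                                seed = 1, sec_prob = 0.5) {
  set.seed(seed)
  pid <- sprintf("P%04d", seq_len(n))
  dom <- sample(genes, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    out <- tibble::tibble(patient_id = pid[i], gene = dom[i],
      label = "dominant", cluster = 1L, tcf = runif(1, 0.5, 0.9))
    if (runif(1) < sec_prob) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        patient_id = pid[i], gene = sample(genes, 1), label = "secondary",
        cluster = 2L, tcf = runif(1, 0.05, 0.4)))
    }
    out
  })
  arch <- dplyr::bind_rows(rows)
  arch$vaf_obs <- arch$tcf / 2
  clinical <- tibble::tibble(
    patient_id = pid,
    diagnosis = sample(c("MDS", "MDS_MPN"), n, TRUE, prob = c(0.85, 0.15)),
    ipssr_score = round(runif(n, 0.5, 9), 1),
    os_months = round(rexp(n, log(2) / 27), 2),
    os_event = runif(n) < 0.7,
    hma_treated = runif(n) < 0.3,
    hma_response = NA_character_
  )
  treated <- which(clinical$hma_treated)
  clinical$hma_response[treated] <- sample(c("CR", "PR", "HI", "none"),
    length(treated), TRUE, prob = c(0.15, 0.1, 0.1, 0.65))
  clinical <- clonehier:::derive_risk_group(clinical)
  list(architecture = arch, clinical = clinical)
}

# independent brute-force two-sided Fisher p over all tables with the
# observed margins, using log-binomial coefficients (oracle)
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  probs <- exp(logp)
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
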