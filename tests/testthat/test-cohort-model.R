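test_that("mutation table reading computes VAF from counts and validates", {
  path <- write_mutation_tsv(c(
    "P1\tTET2\tmissense\t4\t106000100\tA\tT\t40\t100\tTRUE",
    "P1\tsf3b1\ttruncating\t2\t198000000\tG\tC\t10\t50\tTRUE"
  ))
  calls <- read_mutation_table(path)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$vaf_obs[1], 0.40)
  expect_equal(calls$gene[2], "SF3B1") # case-normalized

  empty <- read_mutation_table(write_mutation_tsv(character(0)))
  expect_equal(nrow(empty), 0)

  bad <- write_mutation_tsv("P1\tTET2\tmissense\t4\t1\tA\tT\t120\t100\tTRUE")
  expect_error(read_mutation_table(bad), class = "clonehier_validation_error")

  # missing column named in the error
  path2 <- tempfile(fileext = ".tsv")
  writeLines("patient_id\tgene\tchrom\tpos", path2)
  err <- tryCatch(read_mutation_table(path2), error = identity)
  expect_s3_class(err, "clonehier_schema_error")
  expect_match(conditionMessage(err), "alt_reads")
})

test_that("single-sample VCF records with AD/DP are ingested", {
  skip_if_not_installed("vcfR")
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1",
    "4\t106000100\t.\tA\tT\t.\tPASS\tGENE=tet2\tGT:AD:DP\t0/1:60,40:100"
  ), path)
  calls <- read_mutation_table(path, format = "vcf")
  expect_equal(calls$patient_id, "P1")
  expect_equal(calls$gene, "TET2")
  expect_equal(calls$alt_reads, 40L)
  expect_equal(calls$depth, 100L)
  expect_equal(calls$vaf_obs, 0.4)
})

test_that("variant filters apply the depth/alt/bidirectional rules inclusively", {
  calls <- tibble::tibble(
    patient_id = "P1", gene = "TET2",
    alt_reads = c(10, 5, 4, 8, 30),
    depth = c(19, 20, 500, 100, 100),
    bidirectional = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  kept <- filter_variants(calls)
  expect_equal(kept$depth, c(20, 100))

  # idempotent
  expect_identical(filter_variants(kept), kept)

  # invariant over a generated cohort
  sim <- simulate_cohort(sim_config(n_patients = 80, seed = 11))
  f <- filter_variants(sim$mutations)
  expect_true(all(f$depth >= 20 & f$alt_reads >= 5 & f$bidirectional))
})

test_that("SEG reading enforces the copy-state invariants and matching is point-in-interval", {
  seg_path <- tempfile(fileext = ".seg")
  writeLines(c(
    "sample\tchrom\tstart\tend\tregion_class\ttcn\tascn",
    "P1\t5\t100\t200\tdeletion\t1\t0",
    "P1\t4\t50\t90\tUPD\t2\t0"
  ), seg_path)
  seg <- read_seg(seg_path)
  expect_equal(nrow(seg), 2)

  calls <- tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P2"),
    chrom = c("5", "5", "4", "5"),
    pos = c(100, 201, 70, 150), # boundary inclusive; 201 outside
    gene = "X", vaf_obs = 0.3
  )
  m <- match_cn_state(calls, seg)
  expect_equal(m$region_class, c("deletion", "neutral", "UPD", "neutral"))

  bad <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tregion_class\ttcn\tascn",
    "P1\t5\t1\t2\tneutral\t3\t1"), bad)
  expect_error(read_seg(bad), class = "clonehier_validation_error")
})

test_that("clinical reading derives the 3.5 risk split and checks response consistency", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "patient_id\tdiagnosis\tipssr_score\tos_months\tos_event\thma_treated\thma_response",
    "P1\tMDS\t3.5\t20\tTRUE\tTRUE\tCR",
    "P2\tMDS_MPN\t3.6\t10\tFALSE\tFALSE\tNA"
  ), path)
  clin <- read_clinical(path)
  expect_equal(clin$risk_group, c("low", "high"))

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "patient_id\tdiagnosis\tipssr_score\tos_months\tos_event\thma_treated\thma_response",
    "P1\tMDS\t2\t20\tTRUE\tFALSE\tCR"
  ), path2)
  expect_error(read_clinical(path2), class = "clonehier_validation_error")
})

test_that("result writing is deterministic and round-trips mutation tables", {
  sim <- simulate_cohort(sim_config(n_patients = 20, seed = 3))
  dir1 <- tempfile(); dir2 <- tempfile()
  man1 <- write_results(list(mutations = sim$mutations), dir1,
    config = list(seed = 3))
  write_results(list(mutations = sim$mutations), dir2,
    config = list(seed = 3))
  expect_equal(man1$rows, nrow(sim$mutations))
  expect_identical(
    readBin(file.path(dir1, "mutations.tsv"), "raw", 1e6),
    readBin(file.path(dir2, "mutations.tsv"), "raw", 1e6)
  )
  # round trip preserves all reader fields
  back <- read_mutation_table(file.path(dir1, "mutations.tsv"))
  shared <- intersect(names(back), names(sim$mutations))
  expect_equal(as.data.frame(back[shared]),
    as.data.frame(sim$mutations[shared]))

  # empty table set -> empty manifest
  man0 <- write_results(list(), tempfile())
  expect_equal(nrow(man0), 0)
})
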