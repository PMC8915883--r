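# Clonotype table parsing, collapsing, filtering, translation and
# segment-name normalization.

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a VDJtools-style table parses row for row, missing D accepted", {
  path <- write_tmp_tsv(c(
    "count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj",
    "3\t0.6\tTGTGCCTTC\tCAF\tTRBV20-1*01\t.\tTRBJ2-1",
    "2\t0.4\tTGTAAGTTC\tCKF\tTRBV28\tTRBD1\tTRBJ2-7"
  ))
  rep <- suppressMessages(read_clonotype_table(
    path, donor_id = "d1", subset = "CD4", chain = "TRB", condition = "case"))
  expect_s3_class(rep, "tcr_repertoire")
  expect_equal(diversity(rep), 2L)
  expect_equal(rep$clonotypes$d_segment, c(MISSING_SEGMENT, "TRBD1"))
  # allele suffix stripped at read time
  expect_equal(rep$clonotypes$v_segment[1], "TRBV20-1")
  expect_equal(rep$donor_id, "d1")
})

test_that("the MIXCR export dialect maps its column names", {
  path <- write_tmp_tsv(c(
    paste("cloneCount", "cloneFraction", "nSeqCDR3", "aaSeqCDR3",
          "bestVHit", "bestDHit", "bestJHit", sep = "\t"),
    paste("5", "1.0", "TGTGCCTTC", "CAF", "TRBV9*00(912)", "", "TRBJ1-1*00",
          sep = "\t")
  ))
  rep <- suppressMessages(read_clonotype_table(path, dialect = "mixcr"))
  expect_equal(rep$clonotypes$v_segment, "TRBV9")
  expect_equal(rep$clonotypes$d_segment, MISSING_SEGMENT)
  expect_equal(rep$clonotypes$count, 5L)
})

test_that("malformed tables raise typed errors", {
  no_col <- write_tmp_tsv(c(
    "count\tfreq\tcdr3nt\tv\td\tj",
    "3\t1.0\tTGTGCCTTC\tTRBV9\t.\tTRBJ1-1"
  ))
  expect_error(read_clonotype_table(no_col), class = "tcrcomp_format_error",
               regexp = "cdr3aa")
  header_only <- write_tmp_tsv("count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj")
  expect_error(read_clonotype_table(header_only),
               class = "tcrcomp_empty_error")
  bad_count <- write_tmp_tsv(c(
    "count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj",
    "3\t0.5\tTGTGCCTTC\tCAF\tTRBV9\t.\tTRBJ1-1",
    "x\t0.5\tTGTAAGTTC\tCKF\tTRBV9\t.\tTRBJ1-1"
  ))
  expect_error(read_clonotype_table(bad_count),
               class = "tcrcomp_parse_error", regexp = "Row 2")
  expect_error(read_clonotype_table("/nonexistent/file.tsv"),
               class = "tcrcomp_format_error")
})

test_that("merge_clonotypes combines identical keys and keeps distinct ones", {
  recs <- tibble::tibble(
    cdr3_nt = c("TGTGCCTTC", "TGTGCCTTC", "TGTGCCTTC"),
    cdr3_aa = "CAF",
    v_segment = c("TRBV9", "TRBV9", "TRBV28"),
    d_segment = ".", j_segment = "TRBJ1-1",
    count = c(3L, 2L, 1L), frequency = NA_real_
  )
  merged <- merge_clonotypes(recs)
  expect_equal(nrow(merged), 2L)           # V is part of the identity key
  expect_equal(merged$count[merged$v_segment == "TRBV9"], 5L)
  expect_equal(sum(merged$frequency), 1, tolerance = 1e-12)
  # single-key degenerate case: frequency 1
  one <- merge_clonotypes(recs[1:2, ])
  expect_equal(one$count, 5L)
  expect_equal(one$frequency, 1)
  # empty input passes through
  expect_equal(nrow(merge_clonotypes(recs[0, ])), 0L)
})

test_that("merge_clonotypes is idempotent, conserves counts, flags aa conflicts", {
  withr::local_seed(11)
  for (i in 1:10) {
    recs <- random_records(40)
    merged <- merge_clonotypes(recs)
    expect_equal(sum(merged$count), sum(recs$count))
    expect_identical(merge_clonotypes(merged), merged)
    # identity keys unique after merging
    key <- paste(merged$v_segment, merged$d_segment, merged$j_segment,
                 merged$cdr3_nt)
    expect_false(any(duplicated(key)))
  }
  conflict <- tibble::tibble(
    cdr3_nt = "TGTGCCTTC", cdr3_aa = c("CAF", "XAF"),
    v_segment = "TRBV9", d_segment = ".", j_segment = "TRBJ1-1",
    count = 1L, frequency = NA_real_
  )
  expect_error(merge_clonotypes(conflict), class = "tcrcomp_integrity_error")
})

test_that("filter_functional removes stop and frameshift clonotypes only", {
  recs <- tibble::tibble(
    cdr3_nt = c("TGTGCCAGCAGCTAAGGATTC", "TGTGCCAGCAGCCTGAAAGGATGGTTC",
                "TGTGCCAGCAGCCTGGGATGGTT"),
    cdr3_aa = c("CASS*GF", "CASSLKGWF", "CASSLGW_"),
    v_segment = "TRBV9", d_segment = ".", j_segment = "TRBJ1-1",
    count = c(2L, 3L, 5L), frequency = NA_real_
  )
  out <- suppressMessages(filter_functional(recs))
  expect_equal(out$cdr3_aa, "CASSLKGWF")
  expect_equal(out$frequency, 1)
  # all-non-functional input yields empty repertoire with a warning
  expect_warning(
    suppressMessages(empty <- filter_functional(recs[c(1, 3), ])),
    "non-functional"
  )
  expect_equal(nrow(empty), 0L)
  # all-functional input is untouched
  ok <- merge_clonotypes(recs[2, ])
  expect_identical(suppressMessages(filter_functional(ok)), ok)
})

test_that("filter_functional never grows a repertoire; survivors renormalize", {
  withr::local_seed(23)
  for (i in 1:10) {
    rep <- random_repertoire(30)
    merged <- merge_clonotypes(rep)
    out <- suppressMessages(filter_functional(merged))
    expect_lte(diversity(out), diversity(merged))
    if (diversity(out) > 0) {
      expect_equal(sum(out$clonotypes$frequency), 1, tolerance = 1e-6)
    }
  }
})

test_that("translate_cdr3 follows the standard code with * and _ markers", {
  expect_equal(translate_cdr3("TGTGCC"), "CA")
  expect_equal(translate_cdr3("TGA"), "*")
  expect_equal(translate_cdr3("TGTGC"), "C_")
  expect_equal(translate_cdr3(character(0)), character(0))
  expect_error(translate_cdr3("TGN"), class = "tcrcomp_parse_error")
})

test_that("translation round-trips any back-translated codon choice", {
  withr::local_seed(5)
  for (i in 1:25) {
    aa <- paste(sample(AA_STANDARD, sample(3:12, 1), replace = TRUE),
                collapse = "")
    expect_equal(translate_cdr3(backtranslate_random(aa)), aa)
  }
})

test_that("segment names are normalized to gene level", {
  expect_equal(normalize_segment_name("TRBV20-1*01"), "TRBV20-1")
  expect_equal(normalize_segment_name("TRAV26-1"), "TRAV26-1")
  expect_equal(normalize_segment_name(" TRBV9*00(123) "), "TRBV9")
  expect_equal(normalize_segment_name(c(".", "", "NA", NA)),
               rep(MISSING_SEGMENT, 4))
})

test_that("clonotype tables round-trip through write and read", {
  rep <- merge_clonotypes(random_repertoire(25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(rep, path, provenance = "round-trip test")
  back <- suppressMessages(read_clonotype_table(
    path, donor_id = rep$donor_id, subset = rep$subset, chain = rep$chain,
    condition = rep$condition))
  expect_equal(back$clonotypes$cdr3_nt, rep$clonotypes$cdr3_nt)
  expect_equal(back$clonotypes$count, rep$clonotypes$count)
  expect_equal(back$clonotypes$frequency, rep$clonotypes$frequency,
               tolerance = 1e-9)
})

test_that("manifests read from YAML and drive cohort loading", {
  dir <- withr::local_tempdir()
  rep1 <- merge_clonotypes(random_repertoire(20))
  rep2 <- merge_clonotypes(random_repertoire(20))
  write_clonotype_table(rep1, file.path(dir, "s1.tsv"))
  write_clonotype_table(rep2, file.path(dir, "s2.tsv"))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(samples = list(
    list(path = "s1.tsv", donor_id = "d1", subset = "CD4", chain = "TRB",
         condition = "case"),
    list(path = "s2.tsv", donor_id = "d2", subset = "CD4", chain = "TRB",
         condition = "control")
  )), manifest)
  tbl <- read_sample_manifest(manifest)
  expect_equal(nrow(tbl), 2L)
  cohort <- suppressMessages(read_cohort(manifest))
  expect_length(cohort, 2L)
  expect_equal(cohort[[2]]$condition, "control")
  # a missing file fails up front
  yaml::write_yaml(list(samples = list(
    list(path = "absent.tsv", donor_id = "d3", subset = "CD4",
         chain = "TRB", condition = "case")
  )), manifest)
  expect_error(read_cohort(manifest), class = "tcrcomp_format_error")
})
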