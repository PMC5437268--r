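test_that("a one-row table maps fields directly onto a call set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# candidate calls",
    paste("sample_id", "contig", "position", "ref_allele", "alt_allele",
          "t_ref_count", "t_alt_count", "tumour_f", "t_lod_fstar",
          "judgement", "pop_af", "gene", "protein_change", sep = "\t"),
    paste("S01", "chr1", "100", "A", "T", "95", "5", "0.05", "12.0",
          "KEEP", "", "", "", sep = "\t")), path)
  cs <- read_callstats(path)
  expect_s3_class(cs, "lbseq_calls")
  expect_identical(cs$sample_id, "S01")
  expect_identical(nrow(cs$calls), 1L)
  expect_identical(cs$calls$tumour_f, 0.05)
  expect_identical(cs$calls$t_lod, 12)
  expect_identical(cs$calls$position, 100L)
  expect_true(is.na(cs$calls$pop_af))
  expect_false(cs$calls$flagged)
})

test_that("an empty table with a valid header yields an empty call set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cs0 <- sample_callset("S09")
  write_callstats(cs0, path)
  cs <- read_callstats(path)
  expect_identical(nrow(cs$calls), 0L)
})

test_that("write/read round trip reproduces numeric fields exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    cs <- random_callset(20)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_callstats(cs, path)
    back <- read_callstats(path)
    for (col in c("position", "t_ref_count", "t_alt_count", "tumour_f",
                  "t_lod", "pop_af")) {
      expect_identical(back$calls[[col]], cs$calls[[col]], label = col)
    }
    expect_identical(back$calls$judgement, cs$calls$judgement)
    expect_identical(back$calls$gene, cs$calls$gene)
  }
})

test_that("loading never silently drops rows: calls + parse errors = rows in", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("sample_id", "contig", "position", "ref_allele", "alt_allele",
          "t_ref_count", "t_alt_count", "tumour_f", "t_lod_fstar",
          "judgement", sep = "\t"),
    paste("S01", "chr1", "100", "A", "T", "95", "5", "0.05", "12",
          "KEEP", sep = "\t"),
    paste("S01", "chr1", "200", "A", "T", "oops", "5", "0.05", "3",
          "KEEP", sep = "\t"),          # non-numeric count: parse error
    paste("S01", "chr1", "300", "AT", "T", "95", "5", "0.05", "3",
          "KEEP", sep = "\t"),          # indel-like allele: flagged
    paste("S01", "chr1", "400", "A", "T", "95", "50", "0.05", "3",
          "KEEP", sep = "\t")), path)   # counts/fraction inconsistent: flagged
  cs <- read_callstats(path)
  errs <- attr(cs$calls, "parse_errors")
  expect_identical(nrow(cs$calls) + nrow(errs), 4L)
  expect_identical(errs$line, 3L)  # file line number of the corrupt row
  expect_identical(cs$calls$flagged, c(FALSE, TRUE, TRUE))
})

test_that("a missing required column is reported by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("sample_id", "contig", "position", "ref_allele",
                   "alt_allele", "t_ref_count", "t_alt_count", "tumour_f",
                   "judgement", sep = "\t"), path)
  expect_error(read_callstats(path), "t_lod_fstar")
})

test_that("judgements outside KEEP/REJECT map to REJECT with a warning", {
  calls <- calls_from_lods(c(1, 2), judgement = c("KEEP", "UNKNOWN"))
  expect_warning(cs <- sample_callset("S01", calls), "REJECT")
  expect_identical(cs$calls$judgement, c("KEEP", "REJECT"))
})

test_that("absent pop_af serializes as an empty string", {
  cs <- callset_from_lods(c(1, 2), pop_af = c(NA, 0.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_callstats(cs, path)
  fields <- strsplit(readLines(path), "\t")
  pop_col <- which(fields[[1]] == "pop_af")
  expect_identical(fields[[2]][pop_col], "")
  expect_identical(fields[[3]][pop_col], sprintf("%.17g", 0.25))
})

test_that("truth sets load, and reject duplicates and out-of-range AFs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- paste("patient_id", "contig", "position", "ref_allele",
                  "alt_allele", "bm_af", "source", sep = "\t")
  row1 <- paste("P01", "chr1", "100", "A", "T", "0.47", "clinical_panel",
                sep = "\t")
  row2 <- paste("P01", "chr1", "200", "G", "C", "0.014", "five_gene_panel",
                sep = "\t")
  writeLines(c(header, row1, row2), path)
  truth <- read_truth(path)
  expect_s3_class(truth, "lbseq_truth")
  expect_identical(nrow(truth), 2L)

  writeLines(c(header, row1, row1), path)
  expect_error(read_truth(path), "duplicate")

  writeLines(c(header, sub("0.47", "1.3", row1)), path)
  expect_error(read_truth(path), "\\[0, 1\\]")
})
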