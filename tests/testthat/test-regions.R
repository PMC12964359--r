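tx <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  if (!"scaffold" %in% names(d)) d$scaffold <- rep("chr1", nrow(d))
  d
}

test_that("promoter windows follow the strand-relative 750/250 definition", {
  plus <- build_promoter_regions(
    tx(tss = 10000, strand = "+", transcript_id = "T1", gene_id = "G1"))
  expect_equal(plus$regions$start, 9250L)
  expect_equal(plus$regions$end, 10250L)

  minus <- build_promoter_regions(
    tx(tss = 10000, strand = "-", transcript_id = "T1", gene_id = "G1"))
  expect_equal(minus$regions$start, 9750L)
  expect_equal(minus$regions$end, 10750L)

  expect_equal(plus$window_params, c(upstream = 750L, downstream = 250L))
})

test_that("windows running past the scaffold origin are clipped, not dropped", {
  r <- build_promoter_regions(
    tx(tss = 100, strand = "+", transcript_id = "T1", gene_id = "G1"))
  expect_equal(r$regions$start, 0L)
  expect_equal(r$regions$end, 350L)
})

test_that("one region per valid transcript; bad strand records are rejected with a diagnostic", {
  d <- tx(tss = c(1000, 2000, 3000), strand = c("+", "?", "-"),
          transcript_id = c("T1", "T2", "T3"), gene_id = c("G1", "G1", "G2"))
  expect_warning(r <- build_promoter_regions(d), "unknown strand")
  expect_equal(length(r), 2L)
  expect_setequal(r$regions$transcript_id, c("T1", "T3"))
})

test_that("empty annotation yields an empty region_set with a warning", {
  expect_warning(r <- build_promoter_regions(tx(tss = integer(), strand = character(),
                                                transcript_id = character(),
                                                gene_id = character())),
                 "empty")
  expect_equal(length(r), 0L)
})

test_that("strand symmetry: reflecting coordinates maps + windows onto - windows", {
  # reflect positions around L; a + transcript at tss becomes a - transcript
  # at L - tss, and its window must be the reflection of the + window
  L <- 100000L
  tss <- sample(2000:50000, 20)
  fwd <- build_promoter_regions(
    tx(tss = tss, strand = "+",
       transcript_id = sprintf("F%02d", seq_along(tss)), gene_id = "G1"))
  rev <- build_promoter_regions(
    tx(tss = L - tss, strand = "-",
       transcript_id = sprintf("R%02d", seq_along(tss)), gene_id = "G1"))
  expect_equal(rev$regions$start, L - fwd$regions$end)
  expect_equal(rev$regions$end, L - fwd$regions$start)
})

test_that("region files round-trip exactly, including optional gene_name", {
  d <- tx(tss = c(5000, 9000), strand = c("+", "-"),
          transcript_id = c("T1", "T2"), gene_id = c("G1", "G2"),
          gene_name = c("ALPHA", NA))
  r <- build_promoter_regions(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_region_file(r, path)
  r2 <- load_region_file(path)
  expect_equal(as.data.frame(r2$regions), as.data.frame(r$regions))
  expect_identical(r2$window_params, "user-provided")

  # empty set gives a header-only file that loads back empty
  empty <- suppressWarnings(build_promoter_regions(
    tx(tss = integer(), strand = character(), transcript_id = character(),
       gene_id = character())))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_region_file(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
  expect_equal(length(load_region_file(p2)), 0L)
})

test_that("malformed region files are rejected with a precise error", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scaffold\tstart\tend\ttranscript_id",
               "chr1\t1\t100\tT1"), p)
  expect_error(load_region_file(p), "missing column gene_id")

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scaffold\tstart\tend\ttranscript_id\tgene_id",
               "chr1\t100\t200\tT1\tG1",
               "chr1\t500\t400\tT2\tG1"), p2)
  expect_error(load_region_file(p2), "row 2")
})
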