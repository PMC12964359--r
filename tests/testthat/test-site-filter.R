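reg1 <- function() {
  r <- data.frame(scaffold = "chr1", start = 100L, end = 200L,
                  transcript_id = "T1", gene_id = "G1",
                  gene_name = NA_character_, stringsAsFactors = FALSE)
  r
}

site <- function(start, end, tf = "A", score = 500L, scaffold = "chr1") {
  data.frame(scaffold = scaffold, start = as.integer(start), end = as.integer(end),
             tf_name = tf, score = as.integer(score), stringsAsFactors = FALSE)
}

test_that("only the best-scoring site is retained per region and TF", {
  sites <- rbind(site(120, 130, score = 500), site(150, 160, score = 620))
  got <- best_hit_per_region_tf(reg1(), sites, 400)
  expect_equal(nrow(got), 1L)
  expect_equal(got$best_score, 620L)
})

test_that("best hits below the minimum score threshold are dropped", {
  got <- best_hit_per_region_tf(reg1(), site(120, 130, score = 399), 400)
  expect_equal(nrow(got), 0L)
  # threshold 0 keeps everything
  got0 <- best_hit_per_region_tf(reg1(), site(120, 130, score = 399), 0)
  expect_equal(nrow(got0), 1L)
})

test_that("a single-base boundary overlap counts as a match", {
  # [90,105) straddles the region start and outscores the interior site
  sites <- rbind(site(90, 105, score = 700), site(150, 160, score = 620))
  got <- best_hit_per_region_tf(reg1(), sites, 400)
  expect_equal(got$best_score, 700L)
  # half-open: a site ending exactly at the region start does not overlap
  got2 <- best_hit_per_region_tf(reg1(), site(50, 100, score = 900), 400)
  expect_equal(nrow(got2), 0L)
})

test_that("score ties resolve to the smallest start, then smallest end", {
  sites <- rbind(site(150, 160, score = 700), site(120, 130, score = 700))
  got <- best_hit_per_region_tf(reg1(), sites, 400)
  expect_equal(nrow(got), 1L)
  # verify against the oracle which encodes the same deterministic rule
  expect_equal(as_plain_matches(got),
               oracle_best_hits(reg1(), sites, 400))
})

test_that("indexed filtering equals the all-pairs brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:20) {
    inst <- random_overlap_instance(n_regions = sample(5:40, 1),
                                    n_sites = sample(20:300, 1))
    thr <- sample(c(0L, 300L, 400L, 700L), 1)
    got <- best_hit_per_region_tf(inst$regions, inst$sites, thr)
    expect_equal(as_plain_matches(got), oracle_best_hits(inst$regions, inst$sites, thr))
  }
})

test_that("raising the threshold never adds rows (monotonicity)", {
  set.seed(7)
  inst <- random_overlap_instance(n_regions = 30, n_sites = 200)
  lo <- best_hit_per_region_tf(inst$regions, inst$sites, 300)
  hi <- best_hit_per_region_tf(inst$regions, inst$sites, 600)
  key <- function(m) paste(m$tf_name, m$transcript_id)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("read_sites parses BED5 tracks, filters TFs and skips malformed rows", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tA\t500",
               "chr1\t30\t40\tB\t600",
               "chr1\t50\t45\tA\t700",    # end <= start
               "chr1\t60\t70\tA\tnope",   # unparseable score
               "chr2\t10\t20\tA\t800"), p)
  expect_warning(got <- read_sites(p), "skipped 2")
  expect_equal(nrow(got), 3L)
  expect_equal(attr(got, "n_skipped"), 2L)

  filtered <- suppressWarnings(read_sites(p, tf_filter = "A"))
  expect_equal(nrow(filtered), 2L)
  expect_true(all(filtered$tf_name == "A"))

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_sites(empty)), 0L)
})

test_that("whole-genome and per-TF track layouts give identical match tables", {
  set.seed(11)
  inst <- random_overlap_instance(n_regions = 30, n_sites = 200)
  dir <- withr::local_tempdir()
  whole <- file.path(dir, "all.bed")
  data.table::fwrite(inst$sites, whole, sep = "\t", col.names = FALSE)
  per_tf <- file.path(dir, "by_tf")
  dir.create(per_tf)
  for (tf in unique(inst$sites$tf_name))
    data.table::fwrite(inst$sites[inst$sites$tf_name == tf, ],
                       file.path(per_tf, paste0(tf, ".bed")),
                       sep = "\t", col.names = FALSE)
  a <- process_sharded(inst$regions, whole, score_threshold = 400)
  b <- process_sharded(inst$regions, per_tf, score_threshold = 400)
  expect_identical(as_plain_matches(a), as_plain_matches(b))
})

test_that("results are invariant to worker count and scaffold partition", {
  set.seed(13)
  inst <- random_overlap_instance(n_regions = 40, n_sites = 300)
  ref <- best_hit_per_region_tf(inst$regions, inst$sites, 400)
  scafs <- unique(inst$regions$scaffold)
  partitions <- list(as.list(scafs), list(scafs),
                     split(scafs, rep(1:2, length.out = length(scafs))))
  for (p in partitions) {
    for (w in c(1L, 4L)) {
      got <- process_sharded(inst$regions, inst$sites, score_threshold = 400,
                             shards = p, workers = w)
      expect_identical(as_plain_matches(got), as_plain_matches(ref))
    }
  }
  # sites on scaffolds with no regions are silently ignored
  extra <- rbind(inst$sites, site(1, 50, scaffold = "chrUn", score = 999))
  got <- process_sharded(inst$regions, extra, score_threshold = 400)
  expect_identical(as_plain_matches(got), as_plain_matches(ref))
})

test_that("a shard list that is not a partition of the region scaffolds errors", {
  regions <- rbind(reg1(), within(reg1(), {scaffold <- "chr2"; transcript_id <- "T2"}))
  expect_error(process_sharded(regions, site(120, 130), shards = list("chr1")),
               "partition")
})
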