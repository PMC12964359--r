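rec <- function(base_id, version, tf_name, species_tag = "human") {
  data.frame(base_id = base_id, version = version, tf_name = tf_name,
             species_tag = species_tag, stringsAsFactors = FALSE)
}

test_that("only the newest version of each motif accession is retained", {
  got <- select_newest_versions(rbind(rec("MA0898", 1, "HMX3"),
                                      rec("MA0898", 2, "HMX3")))
  expect_equal(nrow(got$records), 1L)
  expect_equal(got$records$version, 2L)

  got2 <- select_newest_versions(rbind(rec("X", 3, "A"), rec("X", 1, "A"),
                                       rec("Y", 1, "B")))
  expect_equal(got2$records[order(base_id), version], c(3L, 1L))

  one <- select_newest_versions(rec("Z", 1, "C"))
  expect_equal(nrow(one$records), 1L)

  expect_error(select_newest_versions(rbind(rec("X", 1, "A"), rec("X", 1, "A"))),
               "duplicate")
})

test_that("heterodimer motifs are detected by the :: separator and optionally dropped", {
  cat0 <- select_newest_versions(rbind(rec("M1", 1, "FOS::JUN"),
                                       rec("M2", 1, "GATA1")))
  dropped <- filter_heterodimers(cat0, drop = TRUE)
  expect_equal(dropped$records$tf_name, "GATA1")
  kept <- filter_heterodimers(cat0, drop = FALSE)
  expect_equal(nrow(kept$records), 2L)
  # idempotent, and identity when no heterodimers remain
  expect_equal(filter_heterodimers(dropped, TRUE)$records, dropped$records)
})

test_that("homolog resolution prefers human motifs and discards unmapped vertebrates", {
  hmap <- data.frame(source_name = c("Hmx3", "Sox9"),
                     human_name = c("HMX3", "SOX9"))

  # rename: vertebrate motif with a homolog and no human record
  cat1 <- select_newest_versions(rec("MA0898", 2, "Hmx3", "mouse"))
  got1 <- resolve_homologs(cat1, hmap)
  expect_equal(got1$records$tf_name, "HMX3")
  expect_equal(got1$resolution_report$action, "renamed")

  # drop: the human version of the motif is preferred when present
  cat2 <- select_newest_versions(rbind(rec("MA0898", 2, "Hmx3", "mouse"),
                                       rec("MA0900", 1, "HMX3", "human")))
  got2 <- resolve_homologs(cat2, hmap)
  expect_equal(got2$records$base_id, "MA0900")
  expect_setequal(got2$resolution_report$action,
                  c("dropped_human_present", "kept_human"))

  # discard: no homolog entry at all
  cat3 <- select_newest_versions(rec("MA0999", 1, "Zzz1", "zebrafish"))
  got3 <- resolve_homologs(cat3, hmap)
  expect_equal(nrow(got3$records), 0L)
  expect_equal(got3$resolution_report$action, "dropped_no_homolog")
})

test_that("homolog collisions keep the newest version, then the smallest base_id", {
  hmap <- data.frame(source_name = c("Hmx3", "hmx3b"),
                     human_name = c("HMX3", "HMX3"))
  cat1 <- select_newest_versions(rbind(rec("MA0898", 2, "Hmx3", "mouse"),
                                       rec("MA0777", 1, "hmx3b", "zebrafish")))
  expect_message(got <- resolve_homologs(cat1, hmap), "collision")
  expect_equal(got$records$base_id, "MA0898")  # newer version wins
  expect_equal(got$records$tf_name, "HMX3")
})

test_that("the full initialization chain yields unique human TF names and only shrinks", {
  records <- rbind(rec("MA0001", 1, "TFA"), rec("MA0001", 2, "TFA"),
                   rec("MA0002", 1, "TFA::TFB"), rec("MA0003", 1, "TFB"),
                   rec("MA0004", 1, "Hmx3", "mouse"),
                   rec("MA0005", 1, "Zzz1", "mouse"))
  hmap <- data.frame(source_name = "Hmx3", human_name = "HMX3")
  n_in <- nrow(select_newest_versions(records)$records)
  out <- resolve_catalog(records, hmap, drop_heterodimers = TRUE)
  expect_lte(nrow(out$records), n_in)
  expect_false(anyDuplicated(out$records$tf_name) > 0)
  expect_setequal(out$records$tf_name, c("TFA", "TFB", "HMX3"))
  expect_equal(out$filters_applied,
               c("newest_version", "heterodimers_dropped", "homologs_resolved"))
})
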