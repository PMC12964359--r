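# Independent all-pairs oracle for the best-hit filter, and a random
# instance generator. The oracle scans every (region, site) pair with plain
# base-R logic: half-open intervals overlap iff site_start < region_end and
# site_end > region_start; per (TF, transcript) the best score wins, ties
# going to the smallest site start, then smallest end; rows below the
# threshold are dropped.

oracle_best_hits <- function(regions, sites, threshold) {
  regions <- as.data.frame(regions)
  sites <- as.data.frame(sites)
  if (!"gene_name" %in% names(regions)) regions$gene_name <- NA_character_
  acc <- list()
  for (i in seq_len(nrow(regions))) {
    hit <- sites$scaffold == regions$scaffold[i] &
      sites$start < regions$end[i] & sites$end > regions$start[i]
    if (!any(hit)) next
    sub <- sites[hit, , drop = FALSE]
    # deterministic best pick per TF: max score, then min start, then min end
    sub <- sub[order(sub$tf_name, -sub$score, sub$start, sub$end), , drop = FALSE]
    sub <- sub[!duplicated(sub$tf_name), , drop = FALSE]
    n <- nrow(sub)
    acc[[length(acc) + 1L]] <- list(
      tf_name = sub$tf_name,
      transcript_id = rep(regions$transcript_id[i], n),
      gene_id = rep(regions$gene_id[i], n),
      gene_name = rep(regions$gene_name[i], n),
      best_score = sub$score)
  }
  if (!length(acc)) {
    out <- data.frame(tf_name = character(), transcript_id = character(),
                      gene_id = character(), gene_name = character(),
                      best_score = integer(), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      tf_name = unlist(lapply(acc, `[[`, "tf_name")),
      transcript_id = unlist(lapply(acc, `[[`, "transcript_id")),
      gene_id = unlist(lapply(acc, `[[`, "gene_id")),
      gene_name = unlist(lapply(acc, `[[`, "gene_name")),
      best_score = unlist(lapply(acc, `[[`, "best_score")),
      stringsAsFactors = FALSE)
    out <- out[out$best_score >= threshold, , drop = FALSE]
    out <- out[order(out$tf_name, out$transcript_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

random_overlap_instance <- function(n_regions = NULL, n_sites = NULL) {
  scaffolds <- paste0("chr", 1:3)
  tfs <- paste0("TF", 1:6)
  if (is.null(n_regions)) n_regions <- sample(5:100, 1)
  if (is.null(n_sites)) n_sites <- sample(20:1000, 1)
  r_start <- sample(0:4000, n_regions, replace = TRUE)
  regions <- data.frame(
    scaffold = sample(scaffolds, n_regions, replace = TRUE),
    start = r_start,
    end = r_start + sample(50:1000, n_regions, replace = TRUE),
    transcript_id = sprintf("T%04d", seq_len(n_regions)),
    gene_id = sprintf("G%03d", sample(ceiling(n_regions / 2), n_regions, replace = TRUE)),
    gene_name = NA_character_,
    stringsAsFactors = FALSE)
  s_start <- sample(0:4800, n_sites, replace = TRUE)
  sites <- data.frame(
    scaffold = sample(scaffolds, n_sites, replace = TRUE),
    start = s_start,
    end = s_start + sample(5:30, n_sites, replace = TRUE),
    tf_name = sample(tfs, n_sites, replace = TRUE),
    score = sample(0:1000, n_sites, replace = TRUE),
    stringsAsFactors = FALSE)
  list(regions = regions, sites = sites)
}

# comparison helper: match tables as plain sorted data.frames
as_plain_matches <- function(x) {
  df <- as.data.frame(x)
  df <- df[order(df$tf_name, df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
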