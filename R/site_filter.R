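# The motif stage: intersect binding-site tracks with regions of interest,
# retain the single best-scoring match per (region, TF), apply the minimum
# score threshold. Overlap queries go through GenomicRanges; any >= 1 base
# intersection between a site and a region (half-open coordinates) counts.

SITE_COLS <- c("scaffold", "start", "end", "tf_name", "score")

empty_site_table <- function() {
  data.table(scaffold = character(), start = integer(), end = integer(),
             tf_name = character(), score = integer())
}

empty_match_table <- function() {
  data.table(tf_name = character(), transcript_id = character(),
             gene_id = character(), gene_name = character(),
             best_score = integer())
}

#' Read a binding-site track
#'
#' Reads TF binding sites from a BED5-dialect TSV (no header; columns chrom,
#' start, end, name = TF, score) in either track layout:
#' \itemize{
#'   \item whole-genome: `path` is a single file holding sites for all TFs;
#'   \item per-TF: `path` is a directory with one track file per TF, named
#'     `<TF>.bed` (or `.tsv`/`.bed.gz`).
#' }
#' Malformed rows (wrong field count, unparseable coordinates or score,
#' `end <= start`, negative values) are skipped; the skip count is reported
#' as one aggregated warning and attached as attribute `n_skipped`.
#'
#' @param path track file or per-TF track directory.
#' @param tf_filter optional character vector; restrict to these TF names
#'   (in the per-TF layout, files whose TF is not listed are not read).
#' @return data.table of sites (scaffold, start, end, tf_name, score),
#'   grouped by scaffold.
#' @export
read_sites <- function(path, tf_filter = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(bed|tsv)(\\.gz)?$", full.names = TRUE)
    tf_of <- sub("\\.(bed|tsv)(\\.gz)?$", "", basename(files))
    if (!is.null(tf_filter)) files <- files[tf_of %in% tf_filter]
    parts <- lapply(files, read_sites_file)
    skipped <- sum(vapply(parts, function(p) attr(p, "n_skipped") %||% 0L, integer(1)))
    sites <- if (length(parts)) rbindlist(parts) else empty_site_table()
  } else {
    if (!file.exists(path)) stop("binding-site track not found: ", path)
    sites <- read_sites_file(path)
    skipped <- attr(sites, "n_skipped") %||% 0L
  }
  if (!is.null(tf_filter)) sites <- sites[tf_name %in% tf_filter]
  setorder(sites, scaffold, start, end, tf_name)
  if (skipped > 0L)
    warning(sprintf("skipped %d malformed row(s) in binding-site track", skipped))
  setattr(sites, "n_skipped", skipped)
  sites[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sites_file <- function(path) {
  raw <- tryCatch(
    suppressWarnings(fread(path, sep = "\t", header = FALSE, fill = TRUE,
                           colClasses = "character")),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- empty_site_table()
    setattr(out, "n_skipped", 0L)
    return(out)
  }
  n_in <- nrow(raw)
  if (ncol(raw) < 5L) {
    out <- empty_site_table()
    setattr(out, "n_skipped", n_in)
    return(out)
  }
  dt <- raw[, 1:5]
  setnames(dt, SITE_COLS)
  start <- suppressWarnings(as.integer(dt$start))
  end <- suppressWarnings(as.integer(dt$end))
  score <- suppressWarnings(as.integer(dt$score))
  ok <- !is.na(start) & !is.na(end) & !is.na(score) &
    start >= 0L & end > start & score >= 0L & !is.na(dt$tf_name) & dt$tf_name != ""
  out <- data.table(scaffold = dt$scaffold[ok], start = start[ok], end = end[ok],
                    tf_name = dt$tf_name[ok], score = score[ok])
  setattr(out, "n_skipped", n_in - sum(ok))
  out
}

#' Best-scoring binding site per region and TF
#'
#' Finds all overlaps between regions of interest and binding sites (any
#' intersection of at least one base, half-open coordinates), keeps only the
#' match with the best score for every combination of region and TF, and
#' drops rows whose best score falls below `score_threshold` (default 400,
#' on the track score scale). Score ties resolve to the site with the
#' smallest start, then smallest end, so results do not depend on input
#' order or track layout. Site strand is ignored.
#'
#' @param regions a `region_set` (or its regions table).
#' @param sites data.table of binding sites, as from [read_sites()].
#' @param score_threshold minimum retained best score (default 400).
#' @return A match table with one row per retained (tf_name, transcript_id)
#'   pair: columns tf_name, transcript_id, gene_id, gene_name, best_score,
#'   sorted by (tf_name, transcript_id).
#' @export
best_hit_per_region_tf <- function(regions, sites, score_threshold = 400L) {
  reg <- if (inherits(regions, "region_set")) regions$regions else as.data.table(regions)
  sites <- as.data.table(sites)
  if (nrow(reg) == 0L || nrow(sites) == 0L) return(empty_match_table())
  if (!"gene_name" %in% names(reg)) reg <- copy(reg)[, gene_name := NA_character_]

  levels <- union(unique(reg$scaffold), unique(sites$scaffold))
  reg_gr <- GenomicRanges::GRanges(
    seqnames = factor(reg$scaffold, levels = levels),
    ranges = IRanges::IRanges(start = reg$start + 1L, end = reg$end))
  site_gr <- GenomicRanges::GRanges(
    seqnames = factor(sites$scaffold, levels = levels),
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end))
  hits <- GenomicRanges::findOverlaps(site_gr, reg_gr, ignore.strand = TRUE)

  if (length(hits) == 0L) return(empty_match_table())
  pairs <- data.table(
    tf_name = sites$tf_name[S4Vectors::queryHits(hits)],
    transcript_id = reg$transcript_id[S4Vectors::subjectHits(hits)],
    gene_id = reg$gene_id[S4Vectors::subjectHits(hits)],
    gene_name = reg$gene_name[S4Vectors::subjectHits(hits)],
    best_score = sites$score[S4Vectors::queryHits(hits)],
    site_start = sites$start[S4Vectors::queryHits(hits)],
    site_end = sites$end[S4Vectors::queryHits(hits)])
  setorder(pairs, tf_name, transcript_id, -best_score, site_start, site_end)
  best <- pairs[!duplicated(pairs[, .(tf_name, transcript_id)])]
  best <- best[best_score >= score_threshold,
               .(tf_name, transcript_id, gene_id, gene_name, best_score)]
  setorder(best, tf_name, transcript_id)
  best[]
}

#' Sharded best-hit filtering across scaffolds
#'
#' Partitions the work by scaffold and processes shards (optionally in
#' parallel worker processes), then reassembles the canonical match table.
#' The result is identical to [best_hit_per_region_tf()] on the unsharded
#' input, independent of the shard partition, worker count, and track
#' layout (whole-genome vs per-TF).
#'
#' @param regions a `region_set`.
#' @param track a binding-site table, a whole-genome track file, or a per-TF
#'   track directory (see [read_sites()]).
#' @param score_threshold minimum retained best score (default 400).
#' @param tf_filter optional TF name filter passed to [read_sites()].
#' @param shards optional list of character vectors partitioning the
#'   scaffolds of `regions`; default: one shard per scaffold.
#' @param workers number of parallel worker processes (default 1; fork-based,
#'   falls back to serial where forking is unavailable).
#' @return match table as from [best_hit_per_region_tf()].
#' @export
process_sharded <- function(regions, track, score_threshold = 400L,
                            tf_filter = NULL, shards = NULL, workers = 1L) {
  reg <- if (inherits(regions, "region_set")) regions$regions else as.data.table(regions)
  sites <- if (is.character(track)) read_sites(track, tf_filter) else {
    s <- as.data.table(track)
    if (!is.null(tf_filter)) s <- s[tf_name %in% tf_filter]
    s
  }
  scaffolds <- unique(reg$scaffold)
  if (is.null(shards)) shards <- as.list(scaffolds)
  got <- sort(unname(unlist(shards)))
  if (!identical(got, sort(scaffolds)))
    stop("shards must partition the scaffold set of the regions exactly")
  # scaffolds present in sites but absent from regions are silently ignored

  run_shard <- function(scafs) {
    best_hit_per_region_tf(reg[scaffold %in% scafs],
                           sites[scaffold %in% scafs], score_threshold)
  }
  workers <- max(1L, as.integer(workers))
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(shards, run_shard, mc.cores = workers)
  } else {
    lapply(shards, run_shard)
  }
  failed <- vapply(results, inherits, logical(1), what = "try-error")
  if (any(failed)) stop("shard processing failed: ", results[[which(failed)[1]]])
  out <- rbindlist(results)
  if (nrow(out) == 0L) return(empty_match_table())
  setorder(out, tf_name, transcript_id)
  out[]
}

#' Write a match table
#'
#' TSV with header; columns tf_name, transcript_id, gene_id, gene_name,
#' best_score.
#'
#' @param matches match table.
#' @param path output path.
#' @export
write_match_table <- function(matches, path) {
  fwrite(as.data.table(matches), path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
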