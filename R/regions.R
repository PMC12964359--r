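#' @import data.table
#' @importFrom stats runif
#' @importFrom utils head
NULL

# Column order used by every region table in the package.
REGION_COLS <- c("scaffold", "start", "end", "transcript_id", "gene_id", "gene_name")

new_region_set <- function(regions, window_params) {
  regions <- as.data.table(regions)
  structure(list(regions = regions, window_params = window_params),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  wp <- if (is.character(x$window_params)) {
    x$window_params
  } else {
    sprintf("upstream=%d, downstream=%d",
            x$window_params[["upstream"]], x$window_params[["downstream"]])
  }
  cat(sprintf("region_set: %d regions on %d scaffold(s) [%s]\n",
              nrow(x$regions), data.table::uniqueN(x$regions$scaffold), wp))
  if (nrow(x$regions)) print(head(x$regions, 5))
  invisible(x)
}

#' @export
length.region_set <- function(x) nrow(x$regions)

#' Build promoter windows around transcription start sites
#'
#' Expands each transcript record into a region of interest spanning
#' `upstream` bases upstream to `downstream` bases downstream of its
#' transcription start site (TSS). Upstream/downstream are strand-relative:
#' on the minus strand, upstream means larger coordinates. Coordinates are
#' 0-based, half-open (BED convention). Windows running past position 0 are
#' clipped at 0 so that every valid transcript yields exactly one region.
#'
#' @param transcripts data.frame with columns `scaffold`, `tss` (0-based TSS
#'   position), `strand` (`"+"` or `"-"`), `transcript_id`, `gene_id` and
#'   optionally `gene_name`.
#' @param upstream bases upstream of the TSS (default 750).
#' @param downstream bases downstream of the TSS (default 250).
#' @return A `region_set`: the regions plus the window parameters used.
#'
#' Records with an unknown strand symbol, a negative TSS, or whose clipped
#' window is empty are rejected with a diagnostic warning; the remaining
#' records each produce one region.
#' @examples
#' tx <- data.frame(scaffold = "chr1", tss = 10000, strand = "+",
#'                  transcript_id = "T1", gene_id = "G1")
#' build_promoter_regions(tx)$regions  # [9250, 10250)
#' @export
build_promoter_regions <- function(transcripts, upstream = 750L, downstream = 250L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 0L || downstream < 0L || upstream + downstream <= 0L)
    stop("upstream and downstream must be non-negative and sum to > 0")
  tx <- as.data.table(transcripts)
  required <- c("scaffold", "tss", "strand", "transcript_id", "gene_id")
  missing <- setdiff(required, names(tx))
  if (length(missing))
    stop("transcript annotation is missing column(s): ", paste(missing, collapse = ", "))
  if (!"gene_name" %in% names(tx)) tx[, gene_name := NA_character_]
  if (nrow(tx) == 0L) {
    warning("empty transcript annotation: returning an empty region_set")
    return(new_region_set(empty_region_table(),
                          c(upstream = upstream, downstream = downstream)))
  }
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in annotation: ",
         paste(unique(tx$transcript_id[duplicated(tx$transcript_id)]), collapse = ", "))

  bad_strand <- !tx$strand %in% c("+", "-")
  bad_tss <- tx$tss < 0L
  if (any(bad_strand))
    warning(sprintf("rejected %d record(s) with unknown strand symbol: %s",
                    sum(bad_strand),
                    paste(head(tx$transcript_id[bad_strand], 5), collapse = ", ")))
  if (any(bad_tss & !bad_strand))
    warning(sprintf("rejected %d record(s) with negative tss", sum(bad_tss & !bad_strand)))
  tx <- tx[!bad_strand & !bad_tss]

  tx[, start := ifelse(strand == "+", tss - upstream, tss - downstream)]
  tx[, end := ifelse(strand == "+", tss + downstream, tss + upstream)]
  tx[start < 0L, start := 0L]

  empty <- tx$start >= tx$end
  if (any(empty)) {
    warning(sprintf("rejected %d record(s) whose clipped window is empty: %s",
                    sum(empty), paste(head(tx$transcript_id[empty], 5), collapse = ", ")))
    tx <- tx[!empty]
  }
  regions <- tx[, .(scaffold, start = as.integer(start), end = as.integer(end),
                    transcript_id, gene_id, gene_name)]
  new_region_set(regions, c(upstream = upstream, downstream = downstream))
}

empty_region_table <- function() {
  data.table(scaffold = character(), start = integer(), end = integer(),
             transcript_id = character(), gene_id = character(),
             gene_name = character())
}

#' Load a region file
#'
#' Reads a user-provided region file: a TSV with a header and at least the
#' columns `scaffold`, `start`, `end`, `transcript_id`, `gene_id`
#' (optionally `gene_name` and `strand`). Rows are kept in file order and
#' used verbatim; no window arithmetic is applied. This makes it possible to
#' supply arbitrary regions of interest (for example tentative enhancers)
#' in place of the generated promoter windows.
#'
#' @param path path to the TSV region file.
#' @return A `region_set` with `window_params = "user-provided"`.
#' @export
load_region_file <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  required <- c("scaffold", "start", "end", "transcript_id", "gene_id")
  for (col in required)
    if (!col %in% names(dt)) stop("missing column ", col, " in region file ", path)
  for (col in intersect(c("scaffold", "transcript_id", "gene_id", "gene_name", "strand"),
                        names(dt)))
    set(dt, j = col, value = as.character(dt[[col]]))
  if (nrow(dt)) {
    dt[, start := as.integer(start)]
    dt[, end := as.integer(end)]
    bad <- which(dt$start >= dt$end | dt$start < 0L)
    if (length(bad))
      stop(sprintf("invalid region (start >= end or start < 0) at row %d of %s",
                   bad[1], path))
  }
  if (!"gene_name" %in% names(dt)) dt[, gene_name := NA_character_]
  if (nrow(dt)) dt[gene_name == "", gene_name := NA_character_]
  keep <- c(REGION_COLS, intersect("strand", names(dt)))
  new_region_set(dt[, keep, with = FALSE], "user-provided")
}

#' Write a region file
#'
#' Writes a `region_set` as a TSV with header, round-trippable through
#' [load_region_file()]: loading the written file reproduces the regions
#' exactly. An empty set produces a header-only file.
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_file <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  dt <- copy(regions$regions)
  if (!"gene_name" %in% names(dt)) dt[, gene_name := NA_character_]
  keep <- c(REGION_COLS, intersect("strand", names(dt)))
  fwrite(dt[, keep, with = FALSE], path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Load a transcript annotation table
#'
#' TSV with header and columns `scaffold`, `tss`, `strand`, `transcript_id`,
#' `gene_id`, optional `gene_name`.
#'
#' @param path path to the annotation TSV.
#' @return data.table of transcript records.
#' @export
load_transcript_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  required <- c("scaffold", "tss", "strand", "transcript_id", "gene_id")
  for (col in required)
    if (!col %in% names(dt)) stop("missing column ", col, " in annotation ", path)
  for (col in intersect(c("scaffold", "strand", "transcript_id", "gene_id", "gene_name"),
                        names(dt)))
    set(dt, j = col, value = as.character(dt[[col]]))
  dt[, tss := as.integer(tss)]
  dt
}
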