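# Provenance ledger: a hidden JSON-lines file in the cache directory that
# records, for every input file, where it came from, which database version
# it carries and when it was retrieved. Re-recording a label appends to its
# history, so updates remain auditable across runs. Content hashes (not
# mtimes) decide whether a reused file changed.

LEDGER_BASENAME <- ".provenance.jsonl"

#' Default ledger path inside a cache directory
#'
#' @param cache_dir directory holding cached/downloaded inputs.
#' @return path of the hidden ledger file.
#' @export
ledger_path <- function(cache_dir) file.path(cache_dir, LEDGER_BASENAME)

#' Checksum of a file's content
#'
#' @param path file path.
#' @return MD5 hex digest of the file content.
#' @export
file_checksum <- function(path) {
  if (!file.exists(path)) stop("cannot checksum missing file: ", path)
  unname(tools::md5sum(path))
}

#' Record a file in the provenance ledger
#'
#' Appends a provenance record for `file_label`. Fetched files carry a
#' version string and a UTC retrieval timestamp; user-provided files carry
#' version `"unknown"` and no timestamp (their versions cannot be tracked).
#' Earlier records for the same label are kept as history. A corrupt ledger
#' is renamed aside and a fresh one started, with a warning.
#'
#' @param ledger path of the ledger file (see [ledger_path()]); created if
#'   absent.
#' @param file_label short label identifying the input (e.g.
#'   `"binding_sites"`).
#' @param source `"user-provided"`, or a fetched-from label such as a URL.
#' @param version version string; defaults to `"unknown"` for user-provided
#'   sources.
#' @param checksum content hash; computed with [file_checksum()] when
#'   `file` is given instead.
#' @param file optional path whose checksum to record.
#' @param retrieved_at UTC timestamp string for fetched files; defaults to
#'   the current time unless the source is user-provided.
#' @return the record just written, invisibly.
#' @export
record_file <- function(ledger, file_label, source = "user-provided",
                        version = NULL, checksum = NULL, file = NULL,
                        retrieved_at = NULL) {
  user_provided <- identical(source, "user-provided")
  if (is.null(version)) version <- if (user_provided) "unknown" else
    stop("fetched files must carry a version string")
  if (is.null(checksum)) {
    if (is.null(file)) stop("provide either checksum or file")
    checksum <- file_checksum(file)
  }
  if (is.null(retrieved_at) && !user_provided)
    retrieved_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  rec <- list(file_label = file_label, source = source, version = version,
              checksum = checksum,
              recorded_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  if (!is.null(retrieved_at)) rec$retrieved_at <- retrieved_at
  read_ledger(ledger)  # quarantines a corrupt ledger before we append
  dir.create(dirname(ledger), recursive = TRUE, showWarnings = FALSE)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = ledger, append = TRUE)
  invisible(rec)
}

#' Read the provenance ledger
#'
#' @param ledger ledger file path.
#' @return list keyed by `file_label`; each element is that label's record
#'   history, latest first. Empty list if the ledger is absent.
#' @export
read_ledger <- function(ledger) {
  if (!file.exists(ledger)) return(list())
  lines <- readLines(ledger, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- tryCatch(lapply(lines, jsonlite::fromJSON),
                   error = function(e) NULL)
  if (is.null(recs) ||
      (length(recs) && !all(vapply(recs, function(r)
        all(c("file_label", "source", "version", "checksum") %in% names(r)),
        logical(1))))) {
    aside <- paste0(ledger, ".corrupt-", format(Sys.time(), "%Y%m%d%H%M%S"))
    file.rename(ledger, aside)
    warning("corrupt provenance ledger renamed to ", aside,
            "; starting a fresh ledger")
    return(list())
  }
  out <- list()
  for (r in recs) out[[r$file_label]] <- c(list(r), out[[r$file_label]])
  out
}

#' Show the provenance of all recorded files
#'
#' Prints one line per file label with its latest source, version, retrieval
#' time (or "user-provided") and checksum.
#'
#' @param ledger ledger file path.
#' @return the report lines, invisibly.
#' @export
show_provenance <- function(ledger) {
  recs <- read_ledger(ledger)
  if (length(recs) == 0L) {
    message("no provenance records found at ", ledger)
    return(invisible(character()))
  }
  lines <- vapply(recs, function(history) {
    r <- history[[1]]
    sprintf("%-20s source=%s version=%s retrieved=%s checksum=%s",
            r$file_label, r$source, r$version,
            if (is.null(r$retrieved_at)) "user-provided" else r$retrieved_at,
            r$checksum)
  }, character(1))
  cat(lines, sep = "\n")
  invisible(unname(lines))
}
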