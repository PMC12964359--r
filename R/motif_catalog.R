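# Motif catalog resolution: newest version per motif accession, optional
# heterodimer removal, vertebrate-to-human homolog resolution. The order of
# the three steps follows the initialization stage of the pipeline.

HETERODIMER_SEP <- "::"  # JASPAR names joint-binding motifs "FOS::JUN"

new_motif_catalog <- function(records, filters_applied = character(),
                              resolution_report = NULL) {
  records <- as.data.table(records)
  structure(list(records = records, filters_applied = filters_applied,
                 resolution_report = resolution_report),
            class = "motif_catalog")
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("motif_catalog: %d motifs (%d human), filters: %s\n",
              nrow(x$records), sum(x$records$species_tag == "human"),
              if (length(x$filters_applied)) paste(x$filters_applied, collapse = " -> ")
              else "none"))
  invisible(x)
}

catalog_records <- function(x) {
  if (inherits(x, "motif_catalog")) x$records else as.data.table(x)
}

#' Read a motif catalog table
#'
#' TSV with header and columns `base_id` (motif accession without version,
#' e.g. MA0898), `version` (positive integer), `tf_name`, `species_tag`
#' (`"human"` or any other vertebrate tag).
#'
#' @param path path to the TSV.
#' @return data.table of motif records.
#' @export
read_motif_catalog <- function(path) {
  if (!file.exists(path)) stop("motif catalog not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  required <- c("base_id", "version", "tf_name", "species_tag")
  for (col in required)
    if (!col %in% names(dt)) stop("missing column ", col, " in motif catalog ", path)
  dt[, version := as.integer(version)]
  if (any(dt$version < 1L)) stop("motif versions must be >= 1")
  dt
}

#' Keep only the newest version of each motif
#'
#' Motif databases version their accessions (MA0898.1, MA0898.2, ...); only
#' the newest version of each base accession is used to build the prior.
#'
#' @param records data.frame of motif records (or a `motif_catalog`).
#' @return A `motif_catalog` with one record per `base_id`.
#' @export
select_newest_versions <- function(records) {
  dt <- copy(catalog_records(records))
  if (nrow(dt) && anyDuplicated(dt[, .(base_id, version)]))
    stop("duplicate (base_id, version) pairs in motif records")
  out <- dt[order(base_id, -version), .SD[1L], by = base_id]
  setcolorder(out, names(dt))
  setorder(out, base_id)
  new_motif_catalog(out, "newest_version")
}

#' Optionally remove heterodimer motifs
#'
#' Heterodimer motifs describe two TFs binding jointly and are named with a
#' `::` separator (e.g. `FOS::JUN`). When `drop = TRUE` these records are
#' removed from the catalog.
#'
#' @param catalog a `motif_catalog`.
#' @param drop logical; remove heterodimers? (default TRUE)
#' @return The filtered `motif_catalog`.
#' @export
filter_heterodimers <- function(catalog, drop = TRUE) {
  stopifnot(inherits(catalog, "motif_catalog"))
  if (!drop)
    return(new_motif_catalog(catalog$records,
                             c(catalog$filters_applied, "heterodimers_kept")))
  keep <- !grepl(HETERODIMER_SEP, catalog$records$tf_name, fixed = TRUE)
  new_motif_catalog(catalog$records[keep],
                    c(catalog$filters_applied, "heterodimers_dropped"))
}

#' Resolve vertebrate motifs to human TF names
#'
#' Non-human vertebrate motifs are kept only when a human homolog of the TF
#' is known: motifs are often highly conserved, so this increases the number
#' of TFs in the prior. Rules, applied after uppercasing TF names on both
#' sides (human TF symbols are conventionally uppercase):
#' \itemize{
#'   \item human records pass through untouched;
#'   \item a non-human record whose homolog name already has a human record
#'     in the catalog is dropped (the human version is preferred);
#'   \item a non-human record with a homolog but no human record is renamed
#'     to the human TF name;
#'   \item a non-human record with no homolog entry is discarded.
#' }
#' Two non-human records resolving to the same human name (with no human
#' record present) collide: the newest version is kept, ties broken by
#' lexicographically smallest `base_id`, and the collision is logged.
#'
#' @param catalog a `motif_catalog`.
#' @param homolog_map data.frame with columns `source_name` (vertebrate TF
#'   name) and `human_name`.
#' @return The resolved `motif_catalog`; its `resolution_report` field
#'   tabulates, per input record, the action taken (`kept_human`, `renamed`,
#'   `dropped_human_present`, `dropped_no_homolog`, `dropped_collision`).
#' @export
resolve_homologs <- function(catalog, homolog_map) {
  stopifnot(inherits(catalog, "motif_catalog"))
  map <- as.data.table(homolog_map)
  if (nrow(map) && !all(c("source_name", "human_name") %in% names(map)))
    stop("homolog_map needs columns source_name, human_name")
  dt <- copy(catalog$records)
  dt[, tf_name := toupper(tf_name)]
  if (nrow(map)) {
    map <- map[, .(source_name = toupper(source_name), human_name = toupper(human_name))]
    map <- unique(map, by = "source_name")
  }

  human <- dt[species_tag == "human"]
  other <- dt[species_tag != "human"]
  report <- data.table(base_id = dt$base_id, tf_name = dt$tf_name,
                       action = NA_character_, resolved_name = dt$tf_name)
  report[dt$species_tag == "human", action := "kept_human"]

  if (nrow(other)) {
    hm <- if (nrow(map)) map$human_name[match(other$tf_name, map$source_name)]
          else rep(NA_character_, nrow(other))
    no_hom <- is.na(hm)
    human_present <- !no_hom & hm %in% human$tf_name
    renamed <- !no_hom & !human_present
    report[match(other$base_id[no_hom], base_id), `:=`(
      action = "dropped_no_homolog", resolved_name = NA_character_)]
    report[match(other$base_id[human_present], base_id), `:=`(
      action = "dropped_human_present", resolved_name = hm[human_present])]
    ren <- other[renamed]
    ren[, tf_name := hm[renamed]]
    # collisions among renamed records: newest version, then smallest base_id
    if (nrow(ren) > 1L) {
      setorder(ren, tf_name, -version, base_id)
      lost <- ren[duplicated(tf_name)]
      if (nrow(lost)) {
        message(sprintf("homolog collision: %d record(s) dropped (%s)",
                        nrow(lost), paste(lost$base_id, collapse = ", ")))
        report[match(lost$base_id, base_id), action := "dropped_collision"]
      }
      ren <- ren[!duplicated(tf_name)]
    }
    report[match(ren$base_id, base_id) , `:=`(action = "renamed",
                                              resolved_name = ren$tf_name)]
    out <- rbind(human, ren)
  } else {
    out <- human
  }
  # residual duplicates (two human motifs for one TF): same deterministic rule
  if (nrow(out) > 1L && anyDuplicated(out$tf_name)) {
    setorder(out, tf_name, -version, base_id)
    dup <- out[duplicated(tf_name)]
    message(sprintf("duplicate TF name(s) in catalog: kept newest version, dropped %s",
                    paste(dup$base_id, collapse = ", ")))
    report[match(dup$base_id, base_id), action := "dropped_collision"]
    out <- out[!duplicated(tf_name)]
  }
  setorder(out, base_id)
  new_motif_catalog(out, c(catalog$filters_applied, "homologs_resolved"), report)
}

#' Run the full catalog initialization chain
#'
#' Newest-version selection, optional heterodimer filtering, then homolog
#' resolution. After the chain every entry has a unique (human) TF name.
#'
#' @inheritParams resolve_homologs
#' @param records motif records table.
#' @param drop_heterodimers remove heterodimer motifs? (default TRUE)
#' @return resolved `motif_catalog`.
#' @export
resolve_catalog <- function(records, homolog_map = NULL, drop_heterodimers = TRUE) {
  if (is.null(homolog_map))
    homolog_map <- data.table(source_name = character(), human_name = character())
  cat0 <- select_newest_versions(records)
  cat1 <- filter_heterodimers(cat0, drop = drop_heterodimers)
  resolve_homologs(cat1, homolog_map)
}
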