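# End-to-end pipeline: initialization (catalog resolution), motif stage
# (best-hit filtering) and PPI stage, composed with the defaults of the
# method and with provenance recording.

#' Default run configuration
#'
#' The defaults of the pipeline: promoter windows from 750 bases upstream to
#' 250 bases downstream of the TSS, a minimum binding score of 400 (track
#' score units), heterodimer motifs removed, whole-genome track layout, PPI
#' self-edges included, one worker, priors keyed by gene ID.
#'
#' @param ... named overrides of any default field.
#' @return named list of configuration values.
#' @examples
#' default_config()$upstream  # 750
#' @export
default_config <- function(...) {
  config <- list(
    upstream = 750L,
    downstream = 250L,
    score_threshold = 400L,
    drop_heterodimers = TRUE,
    track_layout = "whole-genome",
    include_self_ppi = TRUE,
    workers = 1L,
    gene_key_kind = "gene_id",
    # input paths (either annotation_file or region_file is required)
    annotation_file = NULL,
    region_file = NULL,
    motif_catalog_file = NULL,
    homolog_map_file = NULL,
    id_to_name_file = NULL,
    track = NULL,
    interactions_file = NULL,
    # outputs
    motif_prior_out = "motif_prior.tsv",
    ppi_prior_out = "ppi_prior.tsv",
    cache_dir = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  config[names(overrides)] <- overrides
  config
}

#' Read a YAML run configuration
#'
#' Fields not present in the file keep their defaults; unknown fields are an
#' error.
#'
#' @param path YAML file.
#' @return configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(default_config, vals)
}

#' Dump a configuration as YAML
#'
#' @param config configuration list.
#' @param path optional output file; when `NULL` the YAML text is returned.
#' @export
write_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(config[!vapply(config, is.null, logical(1))])
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Run the full prior-generation pipeline
#'
#' Executes the three stages in order — initialization (newest motif
#' versions, optional heterodimer filtering, homolog resolution), the motif
#' stage (promoter-window construction or user region file, best-hit
#' binding-site filtering, transcript-to-gene aggregation, optional ID to
#' name conversion) and the PPI stage — writes the motif prior and the PPI
#' prior, and records the provenance of every input. On a hard error any
#' partial output files are removed.
#'
#' @param config configuration from [default_config()] / [read_config()].
#'   Required fields: `motif_catalog_file`, `track`, `interactions_file`,
#'   and one of `annotation_file` / `region_file`.
#' @return invisibly, a list with the `motif_prior`, `ppi_prior`, the match
#'   table and the output paths.
#' @export
run_generate <- function(config = default_config()) {
  required <- c("motif_catalog_file", "track", "interactions_file")
  for (f in required)
    if (is.null(config[[f]])) stop("configuration field ", f, " is required")
  if (is.null(config$annotation_file) && is.null(config$region_file))
    stop("either annotation_file or region_file is required")
  inputs <- c("annotation_file", "region_file", "motif_catalog_file",
              "homolog_map_file", "id_to_name_file", "track",
              "interactions_file")
  for (f in inputs) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("input ", f, " does not exist: ", p)
  }
  outputs <- c(config$motif_prior_out, config$ppi_prior_out)
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))

  # initialization: resolve the motif catalog
  records <- read_motif_catalog(config$motif_catalog_file)
  homolog_map <- if (!is.null(config$homolog_map_file))
    fread(config$homolog_map_file, sep = "\t", header = TRUE) else NULL
  catalog <- resolve_catalog(records, homolog_map,
                             drop_heterodimers = config$drop_heterodimers)
  message(sprintf("catalog resolved: %d TFs", nrow(catalog$records)))

  # motif stage
  regions <- if (!is.null(config$region_file)) {
    load_region_file(config$region_file)
  } else {
    build_promoter_regions(load_transcript_annotation(config$annotation_file),
                           config$upstream, config$downstream)
  }
  message(sprintf("regions of interest: %d", length(regions)))
  matches <- process_sharded(regions, config$track,
                             score_threshold = config$score_threshold,
                             tf_filter = catalog$records$tf_name,
                             workers = config$workers)
  prior <- aggregate_to_genes(matches)
  if (identical(config$gene_key_kind, "gene_name")) {
    if (is.null(config$id_to_name_file))
      stop("gene_key_kind = gene_name requires id_to_name_file")
    prior <- convert_ids_to_names(prior, read_id_to_name(config$id_to_name_file))
  }
  write_motif_prior(prior, config$motif_prior_out)
  message(sprintf("motif prior: %d edges, %d TFs -> %s",
                  nrow(prior$edges), uniqueN(prior$edges$tf_name),
                  config$motif_prior_out))

  # PPI stage: TFs that made it into the motif prior
  prior_tfs <- unique(prior$edges$tf_name)
  ppi <- if (length(prior_tfs)) {
    interactions <- fread(config$interactions_file, sep = "\t", header = TRUE)
    build_ppi(prior_tfs, interactions, include_self = config$include_self_ppi)
  } else {
    warning("motif prior is empty; writing an empty PPI prior")
    new_ppi_prior(data.table(tf_a = character(), tf_b = character(),
                             weight = numeric()))
  }
  write_ppi_prior(ppi, config$ppi_prior_out)
  message(sprintf("PPI prior: %d edges -> %s", nrow(ppi$edges),
                  config$ppi_prior_out))

  # provenance: all inputs are user-provided files in this interface
  if (!is.null(config$cache_dir)) {
    led <- ledger_path(config$cache_dir)
    for (f in inputs) {
      p <- config[[f]]
      if (!is.null(p) && file.exists(p) && !dir.exists(p))
        record_file(led, f, source = "user-provided", file = p)
    }
  }
  ok <- TRUE
  invisible(list(motif_prior = prior, ppi_prior = ppi, matches = matches,
                 motif_prior_out = config$motif_prior_out,
                 ppi_prior_out = config$ppi_prior_out))
}

#' Compare two prior versions or two track versions
#'
#' With two motif priors, computes the edge confusion matrix restricted to
#' shared TFs; with two binding-site tracks, the per-TF score shift.
#' Supplying a mixture of kinds is an error.
#'
#' @param prior_a,prior_b paths to motif prior edge lists (or `motif_prior`
#'   objects).
#' @param track_a,track_b paths to binding-site tracks (or site tables).
#' @param restriction optional scaffold restriction for the score shift.
#' @param gene_key_kind key kind of the prior files (default `"gene_id"`).
#' @param out optional report path ([write_confusion()] /
#'   [write_score_shift()]).
#' @return the `confusion_matrix` or `score_shift` object, invisibly when
#'   `out` is given.
#' @export
run_compare <- function(prior_a = NULL, prior_b = NULL,
                        track_a = NULL, track_b = NULL,
                        restriction = NULL, gene_key_kind = "gene_id",
                        out = NULL) {
  have_priors <- !is.null(prior_a) || !is.null(prior_b)
  have_tracks <- !is.null(track_a) || !is.null(track_b)
  if (have_priors && have_tracks)
    stop("supply two priors or two tracks, not a mixture")
  if (have_priors) {
    if (is.null(prior_a) || is.null(prior_b)) stop("both priors are required")
    if (is.character(prior_a)) prior_a <- read_motif_prior(prior_a, gene_key_kind)
    if (is.character(prior_b)) prior_b <- read_motif_prior(prior_b, gene_key_kind)
    result <- edge_confusion(prior_a, prior_b)
    if (!is.null(out)) { write_confusion(result, out); return(invisible(result)) }
    return(result)
  }
  if (have_tracks) {
    if (is.null(track_a) || is.null(track_b)) stop("both tracks are required")
    if (is.character(track_a)) track_a <- read_sites(track_a)
    if (is.character(track_b)) track_b <- read_sites(track_b)
    result <- score_shift(track_a, track_b, restriction)
    if (!is.null(out)) { write_score_shift(result, out); return(invisible(result)) }
    return(result)
  }
  stop("supply either two priors or two tracks")
}
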