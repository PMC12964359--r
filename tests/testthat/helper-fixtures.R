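# Shared helpers for running the pipeline on generated fixture bundles.

run_fixture_pipeline <- function(fx, ..., workers = 1L) {
  cfg <- default_config(
    annotation_file = fx$annotation, motif_catalog_file = fx$motif_catalog,
    homolog_map_file = fx$homolog_map, track = fx$track,
    interactions_file = fx$interactions,
    motif_prior_out = tempfile(fileext = ".tsv"),
    ppi_prior_out = tempfile(fileext = ".tsv"),
    workers = workers, ...)
  suppressMessages(run_generate(cfg))
}

edges_as_planted <- function(prior) {
  df <- as.data.frame(prior$edges[, c("tf_name", "gene_key")])
  names(df) <- c("tf_name", "gene_id")
  df <- df[order(df$tf_name, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
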