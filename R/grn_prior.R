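# Postprocessing of the match table into the motif prior: transcript-to-gene
# aggregation, optional gene ID -> name conversion with deterministic
# collision handling, and the PANDA-compatible edge-list writer.

new_motif_prior <- function(edges, gene_key_kind) {
  edges <- as.data.table(edges)
  stopifnot(gene_key_kind %in% c("gene_id", "gene_name"))
  structure(list(edges = edges, gene_key_kind = gene_key_kind),
            class = "motif_prior")
}

#' @export
print.motif_prior <- function(x, ...) {
  cat(sprintf("motif_prior: %d edges, %d TFs, %d genes (keyed by %s)\n",
              nrow(x$edges), data.table::uniqueN(x$edges$tf_name),
              data.table::uniqueN(x$edges$gene_key), x$gene_key_kind))
  invisible(x)
}

#' Aggregate transcript matches into gene-level prior edges
#'
#' An edge (TF, gene) is present with weight 1 iff at least one transcript
#' of that gene has a retained best-hit match for the TF. Absent edges are
#' implicit zeros (sparse edge list).
#'
#' @param matches match table from [best_hit_per_region_tf()] or
#'   [process_sharded()].
#' @return A `motif_prior` keyed by `gene_id`.
#' @export
aggregate_to_genes <- function(matches) {
  dt <- as.data.table(matches)
  if (nrow(dt) == 0L)
    return(new_motif_prior(data.table(tf_name = character(),
                                      gene_key = character(),
                                      weight = integer()), "gene_id"))
  edges <- unique(dt[, .(tf_name, gene_key = gene_id)])
  edges[, weight := 1L]
  setorder(edges, tf_name, gene_key)
  new_motif_prior(edges, "gene_id")
}

#' Convert gene IDs to gene names in a motif prior
#'
#' Replaces gene-ID keys by gene names. When several IDs map to the same
#' name, only the ID with the highest number of TF binding sites — measured
#' as distinct TF partners in the prior — keeps its edges; ties break on the
#' lexicographically smallest gene ID (logged). IDs absent from the map keep
#' their ID as key (logged).
#'
#' @param prior a `motif_prior` keyed by `gene_id`.
#' @param id_to_name data.frame with columns `gene_id`, `gene_name`.
#' @return A `motif_prior` keyed by `gene_name`.
#' @export
convert_ids_to_names <- function(prior, id_to_name) {
  stopifnot(inherits(prior, "motif_prior"))
  if (prior$gene_key_kind != "gene_id")
    stop("prior is already keyed by gene_name")
  map <- as.data.table(id_to_name)
  if (!all(c("gene_id", "gene_name") %in% names(map)))
    stop("id_to_name needs columns gene_id, gene_name")
  map <- unique(map[, .(gene_id, gene_name)], by = "gene_id")

  edges <- copy(prior$edges)
  if (nrow(edges) == 0L) return(new_motif_prior(edges, "gene_name"))
  edges[, name := map$gene_name[match(gene_key, map$gene_id)]]
  n_unmapped <- sum(is.na(edges$name))
  if (n_unmapped > 0L) {
    message(sprintf("%d gene ID(s) missing from the name map keep their ID as key",
                    uniqueN(edges$gene_key[is.na(edges$name)])))
    edges[is.na(name), name := gene_key]
  }

  # collision rule: per name, keep the ID with the most distinct TF partners
  partners <- edges[, .(n_tfs = uniqueN(tf_name)), by = .(name, gene_key)]
  setorder(partners, name, -n_tfs, gene_key)
  ties <- partners[, .N, by = name][N > 1L]
  if (nrow(ties)) {
    tie_names <- partners[name %in% ties$name][, .SD[1:2], by = name]
    tied <- tie_names[, .(tie = n_tfs[1] == n_tfs[2]), by = name][tie == TRUE]
    message(sprintf("gene-name collision on %d name(s)%s; keeping the ID with most TF partners",
                    nrow(ties),
                    if (nrow(tied)) sprintf(" (%d tie(s) broken lexicographically)", nrow(tied))
                    else ""))
  }
  keep <- partners[!duplicated(name)]
  edges <- edges[paste(name, gene_key) %in% paste(keep$name, keep$gene_key)]
  out <- edges[, .(tf_name, gene_key = name, weight)]
  setorder(out, tf_name, gene_key)
  new_motif_prior(out, "gene_name")
}

#' Write a motif prior as a PANDA-compatible edge list
#'
#' Headerless, tab-separated, three columns (tf, gene, weight), rows sorted
#' by (tf, gene), so priors from different runs are directly diffable.
#'
#' @param prior a `motif_prior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_prior <- function(prior, path) {
  stopifnot(inherits(prior, "motif_prior"))
  edges <- copy(prior$edges)
  if (nrow(edges) == 0L) {
    warning("writing an empty motif prior")
    file.create(path)
    return(invisible(path))
  }
  setorder(edges, tf_name, gene_key)
  fwrite(edges[, .(tf_name, gene_key, weight)], path, sep = "\t",
         quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a motif prior edge list
#'
#' @param path headerless 3-column TSV (tf, gene, weight).
#' @param gene_key_kind how the gene column is keyed (default `"gene_id"`).
#' @return A `motif_prior`.
#' @export
read_motif_prior <- function(path, gene_key_kind = "gene_id") {
  if (!file.exists(path)) stop("motif prior not found: ", path)
  if (file.size(path) == 0L)
    return(new_motif_prior(data.table(tf_name = character(),
                                      gene_key = character(),
                                      weight = integer()), gene_key_kind))
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = list(character = 1:2))
  if (ncol(dt) != 3L) stop("motif prior must have 3 columns: ", path)
  setnames(dt, c("tf_name", "gene_key", "weight"))
  dt[, weight := as.integer(weight)]
  setorder(dt, tf_name, gene_key)
  new_motif_prior(dt, gene_key_kind)
}

#' Read a gene ID to name map
#'
#' @param path TSV with header and columns `gene_id`, `gene_name`.
#' @return data.table.
#' @export
read_id_to_name <- function(path) {
  if (!file.exists(path)) stop("id-to-name map not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "gene_name") %in% names(dt)))
    stop("id-to-name map needs columns gene_id, gene_name")
  for (col in c("gene_id", "gene_name")) set(dt, j = col, value = as.character(dt[[col]]))
  dt
}
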