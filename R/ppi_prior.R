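# The PPI stage: restrict a protein-interaction table (STRING export
# dialect: protein1, protein2, combined_score on a 0-1000 scale) to the TFs
# present in the motif prior and emit the TF-TF prior edge list.

new_ppi_prior <- function(edges) {
  edges <- as.data.table(edges)
  structure(list(edges = edges), class = "ppi_prior")
}

#' @export
print.ppi_prior <- function(x, ...) {
  cat(sprintf("ppi_prior: %d edges among %d TFs\n", nrow(x$edges),
              data.table::uniqueN(c(x$edges$tf_a, x$edges$tf_b))))
  invisible(x)
}

#' Build a TF-TF PPI prior from an interaction table
#'
#' Keeps interactions whose both endpoints are TFs of interest (matching by
#' uppercase symbol), collapses symmetric duplicates to the maximum score,
#' and rescales combined scores from the 0-1000 database scale to `[0, 1]`
#' (the convention for PANDA PPI priors; disable with `rescale = FALSE`).
#' With `include_self = TRUE` a self-interaction at full confidence is added
#' for every TF, so the prior's diagonal is complete.
#'
#' @param tf_names non-empty character vector of TF names (typically the TFs
#'   present in the motif prior).
#' @param interactions data.frame with columns `protein1`, `protein2`,
#'   `combined_score` (0-1000).
#' @param include_self add (tf, tf) self-edges at full weight? (default TRUE)
#' @param rescale divide combined scores by 1000? (default TRUE)
#' @return A `ppi_prior` of unordered TF pairs with weights.
#' @export
build_ppi <- function(tf_names, interactions, include_self = TRUE, rescale = TRUE) {
  if (length(tf_names) == 0L) stop("tf_names must be non-empty")
  tfs <- sort(unique(toupper(tf_names)))
  dt <- as.data.table(interactions)
  if (nrow(dt) && !all(c("protein1", "protein2", "combined_score") %in% names(dt)))
    stop("interactions need columns protein1, protein2, combined_score")
  scale <- if (rescale) 1000 else 1
  if (nrow(dt)) {
    dt <- dt[, .(a = toupper(protein1), b = toupper(protein2),
                 score = as.numeric(combined_score))]
    dt <- dt[a %in% tfs & b %in% tfs & a != b]
    if (any(dt$score < 0 | dt$score > 1000))
      stop("combined_score must lie in [0, 1000]")
    dt[, `:=`(tf_a = pmin(a, b), tf_b = pmax(a, b))]
    edges <- dt[, .(weight = max(score) / scale), by = .(tf_a, tf_b)]
  } else {
    edges <- data.table(tf_a = character(), tf_b = character(), weight = numeric())
  }
  if (include_self)
    edges <- rbind(edges,
                   data.table(tf_a = tfs, tf_b = tfs, weight = 1000 / scale))
  setorder(edges, tf_a, tf_b)
  new_ppi_prior(edges)
}

#' Write a PPI prior edge list
#'
#' Headerless, tab-separated, three columns (tf_a, tf_b, weight); weights
#' formatted with three decimals; rows sorted.
#'
#' @param prior a `ppi_prior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppi_prior <- function(prior, path) {
  stopifnot(inherits(prior, "ppi_prior"))
  edges <- copy(prior$edges)
  setorder(edges, tf_a, tf_b)
  lines <- sprintf("%s\t%s\t%.3f", edges$tf_a, edges$tf_b, edges$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPI prior edge list
#'
#' @param path headerless 3-column TSV.
#' @return A `ppi_prior`.
#' @export
read_ppi_prior <- function(path) {
  if (!file.exists(path)) stop("PPI prior not found: ", path)
  if (file.size(path) == 0L)
    return(new_ppi_prior(data.table(tf_a = character(), tf_b = character(),
                                    weight = numeric())))
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = list(character = 1:2))
  if (ncol(dt) != 3L) stop("PPI prior must have 3 columns: ", path)
  setnames(dt, c("tf_a", "tf_b", "weight"))
  dt[, weight := as.numeric(weight)]
  setorder(dt, tf_a, tf_b)
  new_ppi_prior(dt)
}
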