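# Prior-version comparison: edge confusion matrix between two motif priors
# (restricted to TFs present in both) and per-TF binding-score shift between
# two track versions.

#' Edge confusion matrix between two motif priors
#'
#' Compares two prior versions over the TF x gene grid spanned by the TFs
#' present in both priors and the union of genes appearing in either prior.
#' Genes lost between versions thereby register as disagreement. Counts:
#' `both` (edge in both priors), `only_a`, `only_b`, `neither`; they always
#' sum to `shared_tfs * gene_universe`.
#'
#' @param prior_a,prior_b `motif_prior` objects with the same
#'   `gene_key_kind`.
#' @return A `confusion_matrix` list with fields `both`, `only_a`, `only_b`,
#'   `neither`, `shared_tfs`, `gene_universe`.
#' @export
edge_confusion <- function(prior_a, prior_b) {
  stopifnot(inherits(prior_a, "motif_prior"), inherits(prior_b, "motif_prior"))
  if (prior_a$gene_key_kind != prior_b$gene_key_kind)
    stop("priors use different gene key kinds (",
         prior_a$gene_key_kind, " vs ", prior_b$gene_key_kind, ")")
  ea <- prior_a$edges; eb <- prior_b$edges
  shared <- intersect(unique(ea$tf_name), unique(eb$tf_name))
  universe <- union(unique(ea$gene_key), unique(eb$gene_key))
  if (length(shared) == 0L) {
    warning("no TFs shared between the two priors: confusion matrix is all zero")
    return(structure(list(both = 0, only_a = 0, only_b = 0, neither = 0,
                          shared_tfs = 0, gene_universe = length(universe)),
                     class = "confusion_matrix"))
  }
  ka <- ea[tf_name %in% shared, paste(tf_name, gene_key, sep = "\r")]
  kb <- eb[tf_name %in% shared, paste(tf_name, gene_key, sep = "\r")]
  both <- length(intersect(ka, kb))
  only_a <- length(setdiff(ka, kb))
  only_b <- length(setdiff(kb, ka))
  total <- length(shared) * length(universe)
  structure(list(both = both, only_a = only_a, only_b = only_b,
                 neither = total - both - only_a - only_b,
                 shared_tfs = length(shared), gene_universe = length(universe)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(paste0("edge confusion over %d shared TFs x %d genes:\n",
                     "  both: %d  only A: %d  only B: %d  neither: %d\n"),
              x$shared_tfs, x$gene_universe,
              x$both, x$only_a, x$only_b, x$neither))
  invisible(x)
}

#' Write a confusion matrix report
#'
#' @param cm a `confusion_matrix`.
#' @param path output path; `.json` writes JSON, anything else a 2-column
#'   TSV of field/value pairs.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(cm), path, auto_unbox = TRUE)
  } else {
    fwrite(data.table(field = names(unclass(cm)),
                      value = unlist(unclass(cm), use.names = FALSE)),
           path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Per-TF binding-score shift between two track versions
#'
#' For every TF with at least one site in both track versions (within the
#' optional scaffold restriction), reports the change in mean site score,
#' new minus old. Distribution means are compared rather than matched
#' individual sites, because site coordinates move when motifs are trimmed
#' between database releases, leaving no stable site-level pairing.
#'
#' @param sites_old,sites_new binding-site tables (see [read_sites()]) on
#'   the same score scale.
#' @param restriction optional character vector of scaffolds to restrict
#'   the comparison to (e.g. a single chromosome).
#' @return A `score_shift` object: `per_tf` table with columns `tf_name`,
#'   `mean_old`, `mean_new`, `shift`, plus the restriction used.
#' @export
score_shift <- function(sites_old, sites_new, restriction = NULL) {
  so <- as.data.table(sites_old); sn <- as.data.table(sites_new)
  if (!is.null(restriction)) {
    so <- so[scaffold %in% restriction]
    sn <- sn[scaffold %in% restriction]
  }
  mo <- so[, .(mean_old = mean(score), n_old = .N), by = tf_name]
  mn <- sn[, .(mean_new = mean(score), n_new = .N), by = tf_name]
  per_tf <- merge(mo, mn, by = "tf_name")  # TFs missing from either version omitted
  per_tf[, shift := mean_new - mean_old]
  setorder(per_tf, tf_name)
  structure(list(per_tf = per_tf[, .(tf_name, mean_old, mean_new, shift)],
                 region_restriction = restriction),
            class = "score_shift")
}

#' @export
print.score_shift <- function(x, ...) {
  cat(sprintf("score_shift: %d TFs%s, mean shift %.2f\n",
              nrow(x$per_tf),
              if (is.null(x$region_restriction)) ""
              else paste0(" (restricted to ",
                          paste(x$region_restriction, collapse = ","), ")"),
              if (nrow(x$per_tf)) mean(x$per_tf$shift) else NA_real_))
  invisible(x)
}

#' Write a per-TF score-shift table
#'
#' @param shift a `score_shift`.
#' @param path output TSV path.
#' @export
write_score_shift <- function(shift, path) {
  stopifnot(inherits(shift, "score_shift"))
  fwrite(shift$per_tf, path, sep = "\t", quote = FALSE)
  invisible(path)
}
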