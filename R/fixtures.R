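# Synthetic fixture generator: fully offline, internally consistent inputs
# for the whole pipeline (annotation, motif catalog, homolog map, id-to-name
# map, binding tracks in both layouts, interaction table) with a planted
# ground-truth edge list that the pipeline must recover exactly.

#' Specification of a synthetic fixture
#'
#' Describes a small synthetic genome with promoter windows, a TF panel, a
#' set of planted TF-to-gene edges (each realized as at least one
#' above-threshold binding site inside a promoter window of the gene) and
#' background sites that must not create edges: they are either placed away
#' from every window or scored below the threshold, with a fixed even split
#' between the two rejection paths so both are exercised.
#'
#' @param n_scaffolds number of scaffolds (named `chr1`, `chr2`, ...).
#' @param n_genes number of genes.
#' @param transcripts_per_gene transcripts per gene (same strand, TSSs a few
#'   dozen bases apart, so their windows overlap).
#' @param n_tfs number of TFs.
#' @param n_planted_edges number of distinct (TF, gene) edges to plant;
#'   ignored when `planted_edges` is given.
#' @param planted_edges optional data.frame (`tf_name`, `gene_id`) of edges
#'   to plant.
#' @param background_site_rate background binding sites per kilobase of
#'   synthetic genome (default 0.2).
#' @param score_pass inclusive integer range of passing scores; its minimum
#'   must be at least `score_threshold`.
#' @param score_fail inclusive integer range of failing scores.
#' @param upstream,downstream,score_threshold pipeline parameters the
#'   fixture is built for (defaults 750 / 250 / 400).
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_scaffolds = 2L, n_genes = 20L,
                         transcripts_per_gene = 2L, n_tfs = 5L,
                         n_planted_edges = 15L, planted_edges = NULL,
                         background_site_rate = 0.2,
                         score_pass = c(400L, 1000L), score_fail = c(0L, 399L),
                         upstream = 750L, downstream = 250L,
                         score_threshold = 400L, seed = 1L) {
  stopifnot(n_scaffolds >= 1L, n_genes >= 1L, transcripts_per_gene >= 1L,
            n_tfs >= 1L, length(score_pass) == 2L, length(score_fail) == 2L)
  if (score_pass[1] < score_threshold)
    stop("minimum passing score must be >= score_threshold")
  if (score_fail[2] >= score_threshold)
    stop("maximum failing score must be < score_threshold")
  spec <- list(n_scaffolds = as.integer(n_scaffolds),
               n_genes = as.integer(n_genes),
               transcripts_per_gene = as.integer(transcripts_per_gene),
               n_tfs = as.integer(n_tfs),
               n_planted_edges = as.integer(n_planted_edges),
               planted_edges = planted_edges,
               background_site_rate = background_site_rate,
               score_pass = as.integer(score_pass),
               score_fail = as.integer(score_fail),
               upstream = as.integer(upstream),
               downstream = as.integer(downstream),
               score_threshold = as.integer(score_threshold),
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Deterministic gene/transcript/TF layout for a spec: genes round-robin over
# scaffolds, promoter slots 4 kb apart, transcript TSSs 50 b apart.
fixture_layout <- function(spec) {
  scaffolds <- paste0("chr", seq_len(spec$n_scaffolds))
  g <- seq_len(spec$n_genes)
  gene_id <- sprintf("G%04d", g)
  gene_scaffold <- scaffolds[(g - 1L) %% spec$n_scaffolds + 1L]
  slot <- (g - 1L) %/% spec$n_scaffolds
  tss_base <- 10000L + slot * 4000L
  strand <- c("+", "-")[g %% 2L + 1L]
  tx <- CJ(gene = g, t = seq_len(spec$transcripts_per_gene))
  tx[, `:=`(scaffold = gene_scaffold[gene],
            tss = tss_base[gene] + (t - 1L) * 50L,
            strand = strand[gene],
            transcript_id = sprintf("T%04d.%d", gene, t),
            gene_id = gene_id[gene],
            gene_name = sprintf("SYN%04d", gene))]
  scaffold_len <- max(tx$tss) + spec$upstream + spec$downstream + 10000L
  list(scaffolds = scaffolds, scaffold_len = scaffold_len,
       gene_id = gene_id,
       tf_names = sprintf("TF%02d", seq_len(spec$n_tfs)),
       transcripts = tx[, .(scaffold, tss, strand, transcript_id,
                            gene_id, gene_name)])
}

# Sites realizing the planted edges plus non-edge-forming background sites.
# Returns the site table, the planted edges and the transcript table.
fixture_sites <- function(spec) {
  lay <- fixture_layout(spec)
  regions <- suppressWarnings(
    build_promoter_regions(lay$transcripts, spec$upstream, spec$downstream))
  reg <- regions$regions

  planted <- if (!is.null(spec$planted_edges)) {
    pe <- as.data.table(spec$planted_edges)
    stopifnot(all(c("tf_name", "gene_id") %in% names(pe)),
              all(pe$tf_name %in% lay$tf_names),
              all(pe$gene_id %in% lay$gene_id))
    unique(pe[, .(tf_name, gene_id)])
  } else {
    all_pairs <- CJ(tf_name = lay$tf_names, gene_id = lay$gene_id)
    if (spec$n_planted_edges > nrow(all_pairs))
      stop("n_planted_edges exceeds the number of distinct (TF, gene) pairs")
    all_pairs[sample.int(nrow(all_pairs), spec$n_planted_edges)]
  }
  setorder(planted, tf_name, gene_id)

  site_w <- 8L
  # one passing site per planted edge, inside the first transcript's window
  first_tx <- reg[!duplicated(gene_id)]
  idx <- match(planted$gene_id, first_tx$gene_id)
  win_start <- first_tx$start[idx]
  win_width <- first_tx$end[idx] - win_start
  offset <- floor(runif(nrow(planted)) * (win_width - site_w))
  planted_sites <- data.table(
    scaffold = first_tx$scaffold[idx],
    start = as.integer(win_start + offset),
    end = as.integer(win_start + offset + site_w),
    tf_name = planted$tf_name,
    score = sample(spec$score_pass[1]:spec$score_pass[2], nrow(planted),
                   replace = TRUE))

  # background: even split between (a) sub-threshold score anywhere and
  # (b) passing score rejection-sampled away from every window
  n_bg <- round(spec$background_site_rate *
                  spec$n_scaffolds * lay$scaffold_len / 1000)
  bg <- NULL
  if (n_bg > 0L) {
    bg_tf <- sample(lay$tf_names, n_bg, replace = TRUE)
    low_path <- seq_len(n_bg) %% 2L == 0L
    bg_scaffold <- sample(lay$scaffolds, n_bg, replace = TRUE)
    bg_start <- integer(n_bg)
    for (i in seq_len(n_bg)) {
      if (low_path[i]) {
        bg_start[i] <- sample.int(lay$scaffold_len - site_w, 1L) - 1L
      } else {
        win <- reg[scaffold == bg_scaffold[i]]
        ok <- FALSE
        for (try in 1:100) {
          s <- sample.int(lay$scaffold_len - site_w, 1L) - 1L
          if (!nrow(win) || !any(s < win$end & s + site_w > win$start)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place a background site away from all windows; ",
                      "the fixture spec is infeasible")
        bg_start[i] <- s
      }
    }
    bg_score <- integer(n_bg)
    bg_score[low_path] <- sample(spec$score_fail[1]:spec$score_fail[2],
                                 sum(low_path), replace = TRUE)
    bg_score[!low_path] <- sample(spec$score_pass[1]:spec$score_pass[2],
                                  sum(!low_path), replace = TRUE)
    bg <- data.table(scaffold = bg_scaffold, start = bg_start,
                     end = bg_start + site_w, tf_name = bg_tf,
                     score = bg_score)
  }
  sites <- rbind(planted_sites, bg)
  setorder(sites, scaffold, start, end, tf_name, score)
  list(sites = sites, planted = planted, layout = lay)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every input the pipeline consumes, in its exact file dialect, to
#' `out_dir`: transcript annotation, motif catalog (with a stale older motif
#' version, a heterodimer and a homolog-less vertebrate decoy, so the
#' catalog-resolution steps all have work to do without changing the TF
#' panel), homolog map, gene ID-to-name map, binding-site track in both
#' layouts (one whole-genome file and a per-TF directory built from the same
#' site set), an interaction table, and the planted ground-truth edge list.
#' Running the pipeline on the bundle with the spec's parameters recovers
#' exactly the planted edges. The same seed yields byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return list of file paths plus `planted` (the ground-truth edge table)
#'   and `tf_names`.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_fixture_seed(spec$seed, {
    fx <- fixture_sites(spec)
    lay <- fx$layout

    paths <- list(
      annotation = file.path(out_dir, "annotation.tsv"),
      motif_catalog = file.path(out_dir, "motif_catalog.tsv"),
      homolog_map = file.path(out_dir, "homolog_map.tsv"),
      id_to_name = file.path(out_dir, "id_to_name.tsv"),
      track = file.path(out_dir, "sites.bed"),
      track_dir = file.path(out_dir, "sites_by_tf"),
      interactions = file.path(out_dir, "interactions.tsv"),
      ground_truth = file.path(out_dir, "ground_truth.tsv"))

    fwrite(fx$layout$transcripts, paths$annotation, sep = "\t", quote = FALSE)

    catalog <- data.table(
      base_id = sprintf("MA%04d", seq_len(spec$n_tfs)),
      version = 2L, tf_name = lay$tf_names, species_tag = "human")
    extras <- data.table(
      base_id = c(sprintf("MA%04d", 1L), "MA9001", "MA9002"),
      version = c(1L, 1L, 1L),
      tf_name = c(lay$tf_names[1], paste0(lay$tf_names[1], "::", lay$tf_names[2]),
                  "Zzz1"),
      species_tag = c("human", "human", "mouse"))
    fwrite(rbind(catalog, extras), paths$motif_catalog, sep = "\t", quote = FALSE)

    fwrite(data.table(source_name = "Xyz2", human_name = "XYZ2"),
           paths$homolog_map, sep = "\t", quote = FALSE)

    fwrite(unique(lay$transcripts[, .(gene_id, gene_name)]),
           paths$id_to_name, sep = "\t", quote = FALSE)

    fwrite(fx$sites, paths$track, sep = "\t", quote = FALSE, col.names = FALSE)
    dir.create(paths$track_dir, showWarnings = FALSE)
    for (tf in lay$tf_names) {
      sub <- fx$sites[tf_name == tf]
      if (nrow(sub))
        fwrite(sub, file.path(paths$track_dir, paste0(tf, ".bed")),
               sep = "\t", quote = FALSE, col.names = FALSE)
    }

    pairs <- CJ(protein1 = lay$tf_names, protein2 = lay$tf_names)[protein1 < protein2]
    keep <- runif(nrow(pairs)) < 0.5
    inter <- pairs[keep]
    inter[, combined_score := sample(150:999, .N, replace = TRUE)]
    fwrite(inter, paths$interactions, sep = "\t", quote = FALSE)

    fwrite(fx$planted, paths$ground_truth, sep = "\t", quote = FALSE)

    c(paths, list(planted = fx$planted, tf_names = lay$tf_names))
  })
}

#' Generate two paired binding-site track versions with planted score shifts
#'
#' Emits a base track ("old") and a second version ("new") whose sites are
#' identical in position but shifted in score by `shift_per_tf` for the
#' listed TFs (other TFs keep their scores). [score_shift()] on the pair
#' recovers the planted shifts exactly.
#'
#' @param spec a [fixture_spec()].
#' @param shift_per_tf named numeric vector: TF name -> score shift added in
#'   the new version.
#' @param out_dir output directory.
#' @return list with `track_old`, `track_new` paths and the shift table.
#' @export
generate_paired_tracks <- function(spec, shift_per_tf, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (length(shift_per_tf) && is.null(names(shift_per_tf)))
    stop("shift_per_tf must be a named vector (TF name -> shift)")
  if (any(!is.finite(shift_per_tf))) stop("shifts must be finite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_fixture_seed(spec$seed, {
    fx <- fixture_sites(spec)
    old <- fx$sites
    new <- copy(old)
    shift <- shift_per_tf[match(new$tf_name, names(shift_per_tf))]
    shift[is.na(shift)] <- 0
    new[, score := as.integer(score + shift)]
    if (any(new$score < 0))
      stop("planted shift would produce negative scores; enlarge score_pass")
    track_old <- file.path(out_dir, "track_old.bed")
    track_new <- file.path(out_dir, "track_new.bed")
    fwrite(old, track_old, sep = "\t", quote = FALSE, col.names = FALSE)
    fwrite(new, track_new, sep = "\t", quote = FALSE, col.names = FALSE)
    tfs <- sort(unique(old$tf_name))
    planted_shift <- unname(shift_per_tf[match(tfs, names(shift_per_tf))])
    planted_shift[is.na(planted_shift)] <- 0
    list(track_old = track_old, track_new = track_new,
         shifts = data.table(tf_name = tfs, shift = planted_shift))
  })
}
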