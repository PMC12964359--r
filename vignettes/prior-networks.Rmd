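---
title: "Building prior regulatory networks from TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building prior regulatory networks from TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnprior)
```

## The problem

Network-inference algorithms of the PANDA family refine a *prior* network —
a map of potential regulation — against experimental expression data. Two
priors are needed: a motif prior (TF → gene edges wherever a TF has a
predicted binding site in a gene's regulatory regions) and a TF–TF
protein–protein interaction (PPI) prior. In practice these priors circulate
between groups for years without updates, even though the underlying motif
and interaction databases are refreshed regularly. `grnprior` makes
regenerating both priors from current database exports a single, scripted,
reproducible step, so that the prior can be rebuilt whenever its sources
change.

The package operates entirely on files: a transcript annotation (or a
user-supplied region file), a versioned motif catalog, genome-wide
binding-site tracks (precomputed motif scans in a BED5 dialect), a
vertebrate-to-human homolog map, and a protein-interaction table in the
STRING export dialect. No network access is needed or attempted; fetching
from live databases is a plug-in point left to the user's scripts, and the
provenance ledger (below) records whatever version strings those scripts
supply.

## The pipeline

`run_generate()` composes three stages.

**Initialization: catalog resolution.** Motif accessions are versioned
(e.g. `MA0898.1`, `MA0898.2`); only the newest version of each accession is
kept (`select_newest_versions()`). Heterodimer motifs — two TFs binding
jointly, named with the `::` separator — are removed by default
(`filter_heterodimers()`); the filter is switchable because heterodimer
edges may be wanted in some applications, but single-TF priors are the
common case for PANDA, so removal is the default. Finally, non-human
vertebrate motifs are resolved through a homolog map
(`resolve_homologs()`): motifs are often strongly conserved, so a
vertebrate motif whose TF has a human homolog is adopted under the human
name — unless the human motif is itself in the catalog, in which case the
human version is preferred and the vertebrate record dropped. A vertebrate
motif with no homolog entry is discarded. After the chain every record has
a unique, uppercase human TF name. Collisions (two vertebrate motifs
resolving to one human name) keep the newest version, then the smallest
accession — an arbitrary but deterministic rule, and logged.

**Motif stage: best-hit filtering.** Regions of interest default to
promoter windows spanning 750 bases upstream to 250 bases downstream of
each transcript's TSS (`build_promoter_regions()`), strand-relative, in
0-based half-open (BED) coordinates — chosen to match the coordinate
convention of the binding-site tracks. Windows crossing position 0 are
clipped rather than dropped, preserving one region per transcript. Any
region file with the same columns can replace the generated windows
(`load_region_file()`), e.g. to use enhancers; user regions are taken
verbatim. Binding sites are intersected with the regions
(`best_hit_per_region_tf()`, backed by `GenomicRanges::findOverlaps`): any
overlap of at least one base counts, since requiring containment would
silently lose sites at window edges. For every (region, TF) combination
only the best-scoring site is retained, and best scores below the threshold
(default 400, on the integer score scale of the tracks) are dropped. Score
ties resolve to the smallest site start, then end, making the result
independent of input order. Site strand is ignored: a predicted site is
evidence of binding potential for the promoter regardless of motif
orientation. Work is partitioned by scaffold (`process_sharded()`) and
optionally fork-parallelized; the output is invariant to the partition, the
worker count, and the track layout (one genome-wide file vs one file per
TF) — equivalences that the test suite asserts rather than assumes.

**Postprocessing and PPI stage.** Transcript-level matches are aggregated
to genes (`aggregate_to_genes()`): a (TF, gene) edge exists iff any
transcript of the gene retained a match, weight 1, absent edges implicit —
the sparse edge list PANDA consumes. Optionally gene IDs are converted to
names (`convert_ids_to_names()`); when several IDs share a name, the ID
with the most distinct TF partners keeps its edges. "Number of TF binding
sites" per gene is read as *distinct TF partners after best-hit collapsing*
(the match table holds at most one site per region × TF by then); raw
pre-collapse site counts would be an alternative reading, but they are not
what the prior is built from. Ties break on the lexicographically smaller
ID. The TFs present in the motif prior are then looked up in the
interaction table (`build_ppi()`): interactions with both endpoints in the
TF set are kept, symmetric duplicates collapse to the maximum score, and
scores are rescaled from the 0–1000 database scale to [0, 1] (the
convention of PANDA PPI priors; `rescale = FALSE` keeps raw scores).
Self-interactions at weight 1 are added by default so the prior's diagonal
is complete. Both priors are written as sorted, headerless, three-column
TSVs — deterministic, hence diffable.

## Comparing prior versions

`edge_confusion()` cross-tabulates two motif priors over the grid of TFs
present in *both* priors × the union of genes appearing in *either* prior.
The union universe is deliberate: a gene present only in the older prior
registers as disagreement rather than vanishing from the comparison.
`score_shift()` reports, per TF, the change in mean site score between two
track versions (new − old), optionally restricted to a scaffold subset.
Means of the per-version score distributions are compared rather than
matched individual sites, because motif trimming between database releases
moves site coordinates and leaves no stable site-level pairing. Both
quantities matter in practice: score distributions drift downward when
motifs are trimmed, which can push TFs below the score threshold and out of
the prior entirely.

## Provenance

Reproducibility of a prior requires knowing exactly which inputs produced
it. `record_file()` appends to a hidden JSON-lines ledger
(`.provenance.jsonl`) in the cache directory: label, source, version,
retrieval time (UTC ISO-8601), and an MD5 content hash. Content hashes, not
modification times, decide whether a reused file changed. Each label keeps
its full history, latest first, so updates remain auditable across runs;
user-provided files are recorded with version `"unknown"`, since their true
version cannot be known. A corrupt ledger is quarantined (renamed aside)
rather than overwritten. `show_provenance()` prints the latest record per
label.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `upstream` | 750 | bases | promoter window extent upstream of the TSS |
| `downstream` | 250 | bases | promoter window extent downstream of the TSS |
| `score_threshold` | 400 | track score units | minimum best score retained |
| `drop_heterodimers` | `TRUE` | — | single-TF priors are the common PANDA use |
| `track_layout` | whole-genome | — | per-TF layout gives identical output |
| `include_self_ppi` | `TRUE` | — | complete diagonal for PANDA message passing |
| `workers` | 1 | processes | fork-based sharding; any count gives the same result |
| `gene_key_kind` | `gene_id` | — | IDs avoid the name-collision rule entirely |

The window and threshold defaults follow current practice for
promoter-proximal motif priors. The threshold is necessarily a compromise:
many predicted sites are not functional, but a prohibitively high cutoff
would remove all sites of TFs with short motifs, whose maximum attainable
score is low. Downstream refinement against expression data is what
ultimately prunes false positives — the prior's job is reasonable coverage,
not precision.

## The fixture generator

`generate_fixture()` builds a fully synthetic, internally consistent input
bundle: a small multi-scaffold genome (`chr1`, `chr2`, ... — the `chr`
dialect is used deliberately to exercise name handling) with promoter slots
4 kb apart, a TF panel, and a planted edge list realized as above-threshold
sites inside promoter windows of the target genes. Background sites are
made harmless through one of two paths, chosen per site with a fixed even
split: a sub-threshold score (anywhere), or a passing score
rejection-sampled away from every window — so both rejection mechanisms of
the filter are exercised. The catalog includes a stale older motif version,
a heterodimer and a homolog-less vertebrate decoy, giving every
initialization step real work without changing the expected TF panel. The
same seed yields byte-identical bundles. `generate_paired_tracks()` emits
two track versions with identical site positions and planted per-TF score
shifts, driving the comparison toolkit's tests.

What the fixtures do *not* emulate: realistic motif score distributions,
overlapping gene neighborhoods (planted promoters are disjoint by
construction, though transcripts of one gene do overlap), sequence content
(the pipeline is purely coordinate-based), or the scale of a real genome.
Passing tests therefore demonstrate the correctness of the filtering,
aggregation and bookkeeping logic under controlled conditions — not
biological validity of any particular prior, which depends on the quality
of the upstream motif scans.

## Numerical and degenerate-input choices

Scores are integers on the track scale; no floating-point comparisons enter
the best-hit rule. All tie-breaks (best-hit site, homolog collision,
gene-name collision) are deterministic and documented above. Empty inputs
degrade gracefully: an empty annotation yields an empty region set with a
warning, a track with no overlapping sites yields an empty match table, an
empty motif prior triggers a warning and an empty PPI prior. Malformed
track rows are skipped and counted rather than fatal, because genome-wide
exports commonly carry stray lines; malformed *region* files, by contrast,
are hard errors naming the column or row, since regions are small,
user-authored, and silently dropping one would corrupt the prior.

The test suite runs the full pipeline on fixtures of up to 200 genes, 20
TFs and 500 planted edges across 5 seeds, checks the indexed overlap engine
against an all-pairs brute-force oracle on 100 random instances of up to
100 regions and 1000 sites, and verifies layout, shard and worker
invariances on the same fixtures — sizes chosen so the properties are
exercised at meaningful scale while the suite stays fast.

## Known limitations

Only promoter-proximal (or user-listed) regions contribute; enhancer
regulation is invisible unless supplied as regions. The prior is
deliberately permissive — predicted binding sites vastly overcount
functional ones. TFs without motifs in the catalog cannot appear. The
pipeline is human-centric in its homolog-resolution direction (vertebrate →
human); other organisms would need a different homolog map and no
resolution step. Binary bigbed tracks must be exported to the text BED
dialect first; a converter is out of scope.

## A worked example

```{r example}
spec <- fixture_spec(n_genes = 20, n_tfs = 5, n_planted_edges = 15, seed = 7)
fx <- generate_fixture(spec, file.path(tempdir(), "fx"))
cfg <- default_config(
  annotation_file = fx$annotation, motif_catalog_file = fx$motif_catalog,
  homolog_map_file = fx$homolog_map, track = fx$track,
  interactions_file = fx$interactions,
  motif_prior_out = file.path(tempdir(), "motif_prior.tsv"),
  ppi_prior_out = file.path(tempdir(), "ppi_prior.tsv"))
res <- run_generate(cfg)
res$motif_prior
res$ppi_prior

# the recovered prior equals the planted truth
identical(res$motif_prior$edges[, paste(tf_name, gene_key)],
          fx$planted[, paste(tf_name, gene_id)])
```
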