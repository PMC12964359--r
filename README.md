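# grnprior

Prior networks for gene regulatory network (GRN) inference. Algorithms of
the PANDA family integrate three inputs: a **motif prior** (TF → gene edges
wherever a transcription factor has a predicted binding site in a gene's
regulatory regions), a **PPI prior** (TF–TF protein–protein interactions)
and expression data. `grnprior` generates the two priors from plain-file
database exports, so they can be rebuilt — reproducibly, with provenance —
whenever the motif or interaction databases are updated, instead of stale
priors circulating for years.

## What it computes

From a transcript annotation, a versioned motif catalog, genome-wide
binding-site tracks and an interaction table:

1. **Catalog resolution** — keep the newest version of each motif
   accession, optionally drop heterodimer motifs (`::`-named), and resolve
   non-human vertebrate motifs to human TF names through a homolog map
   (human motif preferred when both exist; unmapped vertebrate motifs
   discarded).
2. **Motif stage** — build promoter windows `[TSS − 750, TSS + 250)`
   (strand-relative, BED coordinates, user-replaceable by any region file);
   intersect with binding sites; keep the **best-scoring site per (region,
   TF)**; drop best scores below the threshold (default **400**); aggregate
   transcripts into genes. The result is a sparse TF → gene edge list of
   weight-1 edges in PANDA-compatible format. Processing is sharded by
   scaffold and optionally parallel; the output is invariant to worker
   count, shard partition and track layout (one genome-wide file vs one
   file per TF).
3. **PPI stage** — restrict the interaction table to the TFs present in the
   motif prior, collapse symmetric duplicates to the maximum score, rescale
   0–1000 scores to [0, 1], add self-edges at weight 1.

Also included: an **edge confusion matrix** between two prior versions
(restricted to shared TFs, over the union gene universe), a per-TF
**score-shift** report between two track versions, a hidden JSON-lines
**provenance ledger** (versions, retrieval times, content checksums), and a
**synthetic fixture generator** with planted ground-truth edges so the
whole pipeline is testable offline.

## Worked example

```r
library(grnprior)

spec <- fixture_spec(n_genes = 20, n_tfs = 5, n_planted_edges = 15, seed = 7)
fx <- generate_fixture(spec, "fx")

cfg <- default_config(
  annotation_file = fx$annotation, motif_catalog_file = fx$motif_catalog,
  homolog_map_file = fx$homolog_map, track = fx$track,
  interactions_file = fx$interactions,
  motif_prior_out = "motif_prior.tsv", ppi_prior_out = "ppi_prior.tsv",
  cache_dir = "cache")
res <- run_generate(cfg)
#> catalog resolved: 5 TFs
#> regions of interest: 40
#> motif prior: 15 edges, 5 TFs -> motif_prior.tsv
#> PPI prior: 10 edges -> ppi_prior.tsv
```

The 20-gene fixture has 40 transcripts, hence 40 promoter windows; the 15
planted (TF, gene) edges are recovered exactly — background sites either
miss every window or fall below the score threshold. The priors are sorted,
headerless TSVs:

```
$ head -4 motif_prior.tsv        $ head -4 ppi_prior.tsv
TF01    G0008   1                TF01    TF01    1.000
TF01    G0015   1                TF01    TF02    0.401
TF02    G0002   1                TF01    TF04    0.740
TF02    G0011   1                TF01    TF05    0.480
```

Weight-1 motif edges mean "predicted binding in a region of interest"
(absent edges are implicit zeros); PPI weights are database confidence
scores rescaled to [0, 1], with the diagonal at 1. Comparing prior or track
versions:

```r
run_compare(prior_a = "motif_prior.tsv", prior_b = "motif_prior.tsv")
#> edge confusion over 5 shared TFs x 12 genes:
#>   both: 15  only A: 0  only B: 0  neither: 45
show_provenance(ledger_path("cache"))
#> annotation_file      source=user-provided version=unknown retrieved=user-provided checksum=6053d943...
#> ...
```

A command-line wrapper with `generate`, `compare`, `provenance`, `fixture`
and `config` subcommands is installed at
`system.file("cli/grnprior.R", package = "grnprior")`.

See `vignettes/prior-networks.Rmd` for the full account of the method, its
parameters and design choices.

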