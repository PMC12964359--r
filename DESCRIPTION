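Package: grnprior
Title: Prior Gene Regulatory and Protein-Protein Interaction Networks from
    Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds prior networks for gene regulatory network inference
    with PANDA-family algorithms. From a transcript annotation (or a
    user-supplied region file), a versioned transcription-factor motif
    catalog, genome-wide binding-site tracks and a protein-interaction
    table, it derives promoter windows around transcription start sites,
    keeps the best-scoring binding site per region and transcription
    factor above a score threshold, aggregates transcripts into genes and
    writes a sparse TF-to-gene motif prior together with a TF-TF
    protein-protein interaction prior, both as PANDA-compatible edge
    lists. Includes a provenance ledger for input files, a toolkit for
    comparing prior versions (edge confusion matrices and per-TF
    binding-score shifts), and a synthetic-fixture generator with planted
    ground-truth edges for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    parallel,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
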