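Package: beesplice
Title: Alternative Splicing Event Detection and Quantification from
    Splice Junctions and Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and quantifies alternative splicing events (intron
    retention, cassette exons, alternative donor/acceptor sites, and
    alternative first/last exons) from splice-junction calls and per-base
    read coverage, refines gene models with novel exons and intergenic
    transcripts inferred from transcribed islands, scores splice-site
    strength with a maximum-entropy motif model, relates CpG
    observed/expected depletion and bisulfite methylation calls to
    inclusion ratios, and summarizes cross-species conservation of
    alternatively spliced genes.  Ships a synthetic-data generator that
    plants events with known inclusion and splicing ratios so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
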