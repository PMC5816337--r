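Package: dirseq
Title: Differential Intron Retention Analysis from Short- and Long-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies intron retention from per-base read coverage and
    splice-junction counts, calls condition-dependent differential intron
    retention (DIR) events with a pseudo-count-adjusted log-fold-change
    statistic and Benjamini-Hochberg FDR control, classifies alternative
    splicing events (intron retention, alternative donor/acceptor, exon
    skipping, mutually exclusive exons) from long-read isoform models,
    clusters co-regulated retention profiles across stress conditions, and
    converts droplet digital PCR counts into absolute isoform copy numbers
    and retention ratios. Ships a synthetic-data generator that produces
    ground-truth genomes, annotations, coverage, junctions, long-read
    isoform models and droplet counts for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    mclust
Config/testthat/edition: 3
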