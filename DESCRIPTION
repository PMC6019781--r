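Package: plastedit
Title: PPR-Code Target Prediction and C-to-U Editing Analysis for Plastid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning pentatricopeptide-repeat (PPR) editing
    factors to chloroplast C-to-U RNA editing sites. Scores PPR arrays
    against candidate (YC) editing sites genome-wide using an amino-acid
    to nucleotide recognition-code table of log-likelihood ratios,
    normalizes scores to z-scores, and produces reciprocal factor/site
    rankings. Quantifies editing from strand-aware base-count pileups
    with configurable read-count and fraction filters, calls editing
    events induced across an expression series of genotypes, computes
    RPKM over a curated plastid gene set and efficiency-corrected qPCR
    expression ratios, and profiles cis-element divergence between
    species that retain or have lost an editing site. A fully seeded
    synthetic-data generator (genomes with planted targets, binomial
    pileups, count tables, qPCR tables, Mendelian seed segregation)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
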