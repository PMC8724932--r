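Package: lncpept
Title: Discovery of HLA Class I Peptides Encoded by Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteogenomic pipeline for identifying HLA class I presented
    peptides encoded by long noncoding RNAs (lncRNAs). Builds a six-frame
    translated protein search space from a transcript database, filters de
    novo sequenced mass-spectrometry peptides by length and confidence,
    excludes reference-proteome matches, locates surviving peptides in the
    translated space, projects them back to genomic coordinates through
    BED12 block structures, classifies matches by genomic context and source
    lncRNA class, verifies transcript-level expression against RNA-seq
    coverage, applies HLA binding-rank filters, and assesses significance of
    the match count with a decoy-genome binomial-tail empirical p-value.
    Includes a synthetic-fixture generator producing a complete toy universe
    (genome, gene models, lncRNAs, coverage, peptides, rank tables) with
    ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
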