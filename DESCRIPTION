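Package: inodecode
Title: Inosine Codon Decoding, Reporter Peptide Quantification and
    Editing-Site Ribosome Stalling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of adenosine-to-inosine
    (A-to-I) RNA editing at the level of translation. Implements the
    codon-space logic of inosine decoding (expansion of inosine-containing
    codons into their G/A/U decoding variants and classification of which
    decodings are distinguishable at the amino-acid level), construction and
    validation of an in vitro translation reporter with a single
    inosine-containing test codon, in silico LysC digestion and monoisotopic
    peptide masses, concatemer-standard normalization of peptide
    mass-spectrometry intensities into decoding fractions and truncation
    percentages, positional pileup QC of reporter amplicon reads, and
    editing-rate-weighted metagene analysis of ribosome-profiling coverage
    around editing sites. Seeded synthetic-data generators emulate every
    input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
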