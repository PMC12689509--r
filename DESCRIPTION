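Package: thermoscan
Type: Package
Title: Sliding-Window RNA Structure Scanning and Temperature-Differential
    Ensemble Diversity Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transcriptome-scale screening for functional and
    temperature-sensitive RNA secondary structure. Scans transcripts with a
    fixed-size folding window, scores each window's minimum free energy
    against a mononucleotide-shuffled null to obtain thermodynamic z-scores,
    combines window structures into z-weighted consensus models and
    structural motifs, and contrasts partition-function ensemble diversity
    between temperatures (delta-ED) with per-gene and cohort-level
    statistics. Writes browser-ready fixedStep wig and base-pair arc tracks
    with transcript-to-genome coordinate mapping, plus dot-bracket, CT and
    Stockholm structure files. Production folding is delegated to ViennaRNA's
    RNAfold command-line program; a self-contained additive pair-energy
    engine with exact structure enumeration is included as a fast, fully
    reproducible reference model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: ViennaRNA (RNAfold on the PATH) for the production
    folding engine; the bundled reference engine has no system requirements.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
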