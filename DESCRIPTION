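Package: fpkit
Title: Multiscale Footprinting of Tn5 Insertion Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects footprints of DNA-binding proteins from ATAC-style Tn5
    insertion data. Corrects the strong local sequence preference of the Tn5
    transposase with a convolutional model trained on deproteinized (naked)
    DNA, estimates the background dispersion of the centre-versus-flank
    insertion ratio as a function of sequence bias and coverage, and converts
    observed depletion into statistically calibrated multiscale footprint
    scores (window diameters 4-200 bp) that separate transcription-factor-
    and nucleosome-sized protections. Supervised heads predict TF binding
    (classification against ChIP-style labels) and nucleosome occupancy
    (regression against chemical-mapping-style signal) from the multiscale
    footprints. A reduced-scale dilated convolutional sequence model predicts
    multiscale footprints directly from DNA sequence, with per-pseudo-bulk
    low-rank (LoRA) adapters, reference-based per-base attribution scores,
    and in-silico motif perturbation. A seeded synthetic-data generator
    provides ground-truth genomes, bias tables, and insertion data with
    planted protein occupancy for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
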