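Package: primeout
Title: Prime Editing Outcome Classification and Family-Based Off-Target
    Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies prime editing outcomes from single-embryo amplicon
    deep sequencing and screens for the whole-genome mutational footprint of
    transient mismatch-repair inhibition. Reads are demultiplexed by barcode,
    quality-masked, filtered, globally aligned to the wild-type amplicon with
    an affine-gap (Needleman-Wunsch/Gotoh) aligner, and binned as wild-type,
    precise edit, or error within nick-anchored classification windows;
    per-embryo error fractions are calibrated against a normal background
    model fitted on unedited controls, with one-sided z-tests under
    Bonferroni correction and a strict precise-edit detection cutoff.
    A companion family module filters joint-genotyped multi-sample VCFs to
    variants unique to one family member (depth and allele-frequency gated,
    autosomes only), types indels, measures the fraction of -1 bp deletions
    adjacent to poly(A/T) homopolymer tracts, and estimates unique-indel
    fold changes in treated versus control siblings. Synthetic-data
    generators with ground-truth manifests make the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
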