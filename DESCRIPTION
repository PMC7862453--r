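Package: norkit
Title: Simulation and Sequence Analysis of Human Nucleolar Organizer Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the structure and sequence variation of human
    nucleolar organizer regions (NORs), the tandem ribosomal DNA arrays with
    their proximal and distal junction flanks. Provides a synthetic NOR
    generator with ground-truth variants; restriction-site scanning, cloning
    enzyme selection, targeting-hook design and digest fragment prediction for
    recombination-based (TAR) capture of intact rDNA arrays; finishing of
    circular clone assemblies (vector removal, circular-overlap trimming,
    re-orientation, hook verification) and overlap merging into contigs; banded
    affine-gap pairwise alignment of rDNA units with variant calling,
    divergence, sharing and per-region density statistics; RNA secondary
    structure folding with opening free-energy penalties, base-pair distance
    (riboSNitch) scoring, randomization nulls and Mann-Whitney-Wilcoxon tests;
    and relative qPCR copy-number estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
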