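Package: poreImpute
Title: Rule-Based Imputation of Modified k-mer Nanopore Pore Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Summarizes the current-level shifts that DNA base modifications
    (e.g. CpG/GpC methylation, glucosylation) cause in nanopore k-mer
    pore-model tables as a small ordered set of additive "delta-C rules",
    extracted by iterative median-residual fitting, and uses those rules to
    impute complete modified-k-mer tables from partial training data or to
    denoise fully trained tables. Includes readers and writers for the
    Nanopolish/f5c pore-model dialect, reference-genome motif-site scanning
    and coverage-targeted training-site selection, a synthetic-data module
    (random genomes, canonical tables, ground-truth rule sets, noisy trained
    tables), and evaluation utilities for imputation quality and rule
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Epigenetics, Sequencing, Software
RoxygenNote: 7.3.3
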