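Package: insuscreen
Title: Topological Screening for Chromatin Insulator Elements from Hi-C Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for identifying chromatin insulator elements
    from Hi-C contact maps of wild-type versus insulator-protein-knockout
    cells. Provides sparse contact-matrix containers with iterative-correction
    balancing and distance-stratified joint normalization, per-restriction-
    fragment distance-scaling factors (gamma), region-level delta-gamma
    screening against an empirical false-discovery-rate null built from
    random unbound regions, insulator-protein cobinding classification,
    contact-crossing difference curves, an insulator looping test, and a
    synthetic Hi-C generator with implanted boundaries and known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: HiC, Epigenetics, FunctionalGenomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cobinding.R'
    'contacts.R'
    'crossing.R'
    'gamma.R'
    'insuscreen-package.R'
    'io.R'
    'looping.R'
    'screen.R'
    'signals.R'
    'simulate.R'
    'utils.R'
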