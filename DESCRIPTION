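Package: msapclade
Title: MSAP Methylation Typing, Dominant-Marker Phylogenetics and
    Flow-Cytometry Ploidy Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dominant molecular markers in cultivated
    plants. Reads binary band presence/absence matrices from AFLP and
    methylation-sensitive AFLP (MSAP) fingerprinting, classifies MSAP loci
    into the four canonical methylation types from paired EcoRI/HpaII and
    EcoRI/MspI digests, and computes per-sample methylation indices and
    clade-shared/private fragment tallies. Builds neighbor-joining trees
    from Nei-Li band-sharing distances with outgroup rooting and
    locus-resampling bootstrap supports, maps binary morphological
    characters onto a fixed tree by Fitch parsimony with
    synapomorphy/autapomorphy/homoplasy classification, and estimates DNA
    index, 2C value, genome size and ploidy from flow-cytometry
    fluorescence histograms with an internal standard. A seeded synthetic
    data generator produces two-clade marker panels, character matrices
    with planted step counts, and two-peak fluorescence histograms so that
    every stage of the pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
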