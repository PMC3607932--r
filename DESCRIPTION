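Package: TRFLPtools
Title: Terminal Restriction Fragment Community Fingerprinting and
    Diversity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing microbial community composition and
    dynamics from 16S rRNA gene data, built around terminal restriction
    fragment length polymorphism (T-RFLP) fingerprinting of an
    activated-sludge Archaea community. Provides clone-library diversity
    statistics (OTU clustering at nested similarity thresholds, Chao1
    richness, accumulation curves, Pareto-Lorenz evenness and the
    functional organization index), in-silico prediction of labeled
    terminal restriction fragment lengths from sequences and degenerate
    primers, a raw-peak-to-consensus T-RFLP processing pipeline
    (size/height filtering, replicate quality control, moving-average
    peak alignment, iterative fluorescence normalization, consensus
    profiles), community-dynamics statistics (Bray-Curtis distance to
    baseline, dual-enzyme fragment identification against a digest
    database, parameter correlations), fluorescence in situ
    hybridization (FISH) area quantification from labeled channel
    masks, and a synthetic-community generator with controlled ground
    truth so every stage can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
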