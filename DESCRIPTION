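Package: flowcode
Title: Flow-Space Molecular Barcodes for 454 Pyrosequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design, validation and use of error-correcting molecular
    barcodes encoded in 454 pyrosequencing nucleotide flows. Constructs
    minimum-Hamming-distance-3 ternary barcode sets rendered over a fixed
    11-flow window (greedy lexicode and linear [10,7,3] ternary Hamming
    constructions), assembles barcoded A-adapter oligo sheets, demultiplexes
    multiplexed read sets in flow space with optional single-flow-error
    correction, reports cross-contamination and pooling evenness, computes
    equimolar pooling plans, and simulates pyrosequencing reads under a
    flow-level Gaussian noise model so the whole pipeline can be validated
    end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
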