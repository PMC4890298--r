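Package: loopkit
Title: Classes and Methods for Pairwise Genomic Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infrastructure for representing and manipulating pairwise
    genomic interaction data from Hi-C, ChIA-PET and related chromosome
    conformation assays. Provides an anchor-indexed interaction table over
    a deduplicated reference region set, an assay container binding
    interactions to sample-level data matrices, and a contact-matrix view
    with dense and sparse backends. Methods cover one- and two-dimensional
    overlap queries, region linking, anchor distances, minimum bounding
    boxes in the interaction space, bait-centric linearization to a
    4C-like track, lossless interconversion between the interaction-list
    and matrix views, BEDPE/BED/bedGraph interchange, a command-line
    interface, and a seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    S4Vectors,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'regions.R'
    'RegionSet.R'
    'InteractionTable.R'
    'overlaps.R'
    'geometry.R'
    'AssaySet.R'
    'ContactMatrix.R'
    'simulate.R'
    'io.R'
    'cli.R'
    'loopkit-package.R'
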