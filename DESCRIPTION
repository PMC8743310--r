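Package: segatlas
Title: Segment-Resolved Expression Atlases on 3D Organ Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for segment-resolved spatial transcriptomics
    atlases. Maps per-segment gene expression (log2 counts-per-million) onto
    segmented triangle meshes via linear color-gradient interpolation, ranks
    co-expressed (synexpressed) genes by absolute Pearson correlation,
    compares expression patterns per segment (heatmap differences) and per
    segment group (region-of-interest contrasts), and exports colored meshes,
    multi-angle snapshots, ranked tables and chronological session logs.
    Includes a synthetic-data generator with planted spatial patterns and a
    synthetic segmented block mesh for fully reproducible testing, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'expression-io.R'
    'normalize.R'
    'palette.R'
    'analysis.R'
    'mesh-io.R'
    'geometry.R'
    'render.R'
    'session.R'
    'synthetic.R'
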