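Package: scPatchQC
Title: Marker-Based Quality Control for Patch-Seq Single-Cell Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control for single-cell transcriptomes collected with
    patch-seq (combined patch-clamp electrophysiology and RNA-sequencing
    through the recording pipette). Derives "on" and "off" cell type marker
    genes from dissociated-cell reference atlases, scores every patch-seq cell
    for off-target cell type mRNA contamination against dissociated-cell
    baselines, estimates relative mRNA content from ERCC spike-in read
    shares, models how technical factors drive the number of genes detected
    per cell, and propagates a per-cell quality score into weighted
    gene-electrophysiology correlation analyses. Includes a fully
    deterministic synthetic-data generator with planted marker structure,
    mixture contamination, mRNA-content variation against a fixed spike-in
    pool, and gene-coupled electrophysiological features, so the whole
    workflow can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: SingleCell, QualityControl, Transcriptomics, Electrophysiology
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'contamination.R'
    'ephys.R'
    'io.R'
    'markers.R'
    'pipeline.R'
    'scPatchQC-package.R'
    'simulate.R'
    'techFactors.R'
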