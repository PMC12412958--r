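Package: cellmech
Title: Cell Adhesion, Contractility and Confined-Migration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for cell-mechanical phenotyping built
    around four assays: pattern-based contractility screening (closed-form
    contractile energy of a cell contracting a circular micropattern on an
    elastic gel, with a Navier-equation quadrature oracle), single-cell
    force-spectroscopy curve metrics (adhesion energy, adhesion force,
    rupture length, unbinding steps), focal-adhesion and cell-shape
    morphometry (particle counts and sizes, spreading area, aspect ratio,
    circularity, actin filament lengths), and confined-migration track
    statistics (speed, persistence, speed-persistence correlation). Seeded
    synthetic-data generators emulate each assay's raw data with known
    ground truth so the whole pipeline is testable without microscope or
    AFM data, and a reporting layer reproduces the standard two-sample
    t-test conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    pracma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors-show.R'
    'cellmech-package.R'
    'contractility.R'
    'imaging-utils.R'
    'migration.R'
    'morphometry.R'
    'pacs.R'
    'scfs.R'
    'stats.R'
    'synthetic.R'
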