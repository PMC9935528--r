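Package: gloriaqc
Title: Quality Control and Spectral Metrics for Hyperspectral Aquatic
    Reflectance Collections
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating collections of in situ hyperspectral remote
    sensing reflectance (Rrs) from inland and coastal waters distributed in
    the GLORIA multi-file CSV layout. Assembles Rrs from its radiometric
    components (water-leaving radiance and downwelling irradiance, or
    above-water radiance with sky-glint correction), computes the full
    procedural quality-control flag suite (red/blue high-frequency noise,
    baseline shifts, the oxygen A-band imprint near 762 nm, negative
    ultraviolet-blue slopes, QWIP failure) with tri-state missing-coverage
    semantics, derives per-spectrum summary metrics (apparent visible
    wavelength, normalized difference index, QWIP score, CIE chromaticity,
    optical water type assignment), screens water-quality measurements for
    water-type-stratified outliers, and generates labelled synthetic
    hyperspectral datasets so every stage is testable without the archive.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
biocViews: QualityControl, Preprocessing, DataImport
RoxygenNote: 7.3.3
Collate: 
    'gloriaqc-package.R'
    'AllGenerics.R'
    'SpectraSet-class.R'
    'spectra-ops.R'
    'metrics.R'
    'qc-flags.R'
    'io.R'
    'wq-screen.R'
    'synthetic.R'
    'pipeline.R'
    'archive.R'
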