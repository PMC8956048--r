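Package: poriaNIR
Title: NIR Chemometrics for Quality and Origin Assessment of Poria cocos
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Near-infrared spectroscopy chemometrics pipeline for the medicinal
    fungus Poria cocos: spectral pretreatment (standard normal variate,
    multiplicative scatter correction, Savitzky-Golay smoothing and first
    derivative), Monte-Carlo cross-validation outlier elimination,
    Kennard-Stone calibration/validation splitting, NIPALS partial least
    squares regression of four quality parameters (polysaccharides,
    water-soluble and alcohol-soluble extract, sum of five triterpenoid acids)
    with 10-fold cross-validated factor selection and pretreatment grid
    search, random-forest discrimination of three cultivation regions, the
    wet-lab reference arithmetic (gravimetric extract content, standard-curve
    quantification, HPLC calibration with LOD/LOQ), and a region-stratified
    synthetic spectra generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, signal, randomForest
Suggests: testthat (>= 3.0.0), mixOmics, jsonlite, knitr, rmarkdown, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectra-io.R'
    'pretreatment.R'
    'sampling.R'
    'plsr.R'
    'forest.R'
    'chemistry.R'
    'synthetic.R'
    'pipeline.R'
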