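Package: WaveletCalib
Title: Wavelet-Feature Elastic-Net Calibration for Vibrational Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative calibration of component concentrations from 1-D
    absorbance spectra (FTIR and related vibrational spectroscopies) by
    Ricker-wavelet feature expansion followed by sparse elastic-net
    regression with cross-validated hyperparameters (WT-ENCV). Includes
    Gaussian projection of regression coefficients for model
    interpretation, a leakage-free repeated k-fold validation harness,
    conventional peak-based and partial-least-squares baselines, and a
    Beer-Lambert reaction-monitoring spectrum simulator with known ground
    truth. Spectral datasets are held in SummarizedExperiment containers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    mixOmics,
    jsonlite,
    withr,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'baselines.R'
    'cli.R'
    'regression.R'
    'spectra-io.R'
    'synthetic.R'
    'validation.R'
    'visualization.R'
    'wavelet.R'
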