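Package: slicevar
Title: Slice-Dependent Non-Stationary Signal Power in BOLD fMRI Connectivity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models, simulates and corrects slice-dependent non-stationary
    signal power in BOLD fMRI timeseries. Signal power within an EPI slice is
    modelled as an inverse-gamma variance process applied multiplicatively to
    an underlying stationary Gaussian (or vector-autoregressive) signal, which
    makes the marginal voxel intensity a generalized Student's-t distribution.
    Closed-form results quantify the attenuation of pairwise correlation
    (the kappa factor) and the inflation of the sampling variance of sample
    correlation caused by time-varying power, and a precision correction that
    divides each voxel sample by its slice's cross-sectional standard
    deviation restores weak stationarity and the integrity of connectivity
    estimates. The package includes simulation generators for correlated
    white and VAR timeseries pairs and synthetic 4D volumes, per-slice
    variance estimation, maximum-likelihood distribution ranking over nine
    families, augmented Dickey-Fuller stationarity testing, pairwise Wilcoxon
    slice comparisons, tissue-variance association analysis, and seed-voxel
    correlation mapping with Fisher-z significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'adf.R'
    'connectivity.R'
    'correction.R'
    'distributions.R'
    'io.R'
    'statfit.R'
    'theory.R'
    'simulate.R'
    'var-sim.R'
    'pipeline.R'
    'slicevar-package.R'
    'synthetic-bold.R'
    'tissue.R'
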