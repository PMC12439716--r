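Package: nirseed
Title: FT-NIR Seed Quality Calibration for Oilseed Brassica
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and chemometric analysis of Fourier-transform
    near-infrared (FT-NIR) spectra of oilseed Brassica seed, aimed at
    calibration of seed quality traits (oil, protein, glucosinolates,
    phytic acid and seven fatty acids). Provides a seeded synthetic-data
    generator emulating trait-weighted absorbance bands with scatter and
    instrument noise, spectral preprocessing (standard normal variate,
    polynomial detrending, Norris gap-segment derivatives), NIPALS partial
    least squares and principal component regression with cross-validated
    component selection, two-stage outlier screening (Mahalanobis H
    distance in latent-score space and calibration y-residual limits),
    the standard calibration validation statistics (R2, RMSEC and RMSEP,
    MAE, Bias, SEE, SEC, SECV, SEP, RPD), principal component analysis and
    Pearson trait correlations, and randomized-complete-block ANOVA with
    genotypic and phenotypic coefficients of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
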