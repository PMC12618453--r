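Package: dispcann
Title: Automated Discovery of Dispersed Orthotropic Hyperelastic Models for Myocardium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sparse discovery of orthotropic, perfectly incompressible hyperelastic
    constitutive models for myocardium-like tissue with probabilistic fiber, sheet,
    and normal dispersion. Dispersion enters through generalized structure tensors
    built from a pi-periodic von Mises orientation density, summarized by a scalar
    dispersion parameter kappa in [0, 1/3]. A 32-term invariant-based free energy
    (a constitutive neural network) is fitted to triaxial simple-shear and biaxial
    extension Cauchy stress data by L1-regularized Adam optimization with
    non-negativity constraints, yielding interpretable material parameters. Includes
    closed-form protocol stresses, a synthetic data generator for the eleven standard
    loading protocols with controllable Gaussian measurement noise, goodness-of-fit
    reporting, and trainable dispersion parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
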