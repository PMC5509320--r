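Package: bspim
Title: Localization of Atrial Ectopic Beats from Body-Surface P-Wave Integral Maps
Version: 0.1.0
Authors@R: person("BSPiM", "Developers", email = "bspim@example.org", role = c("aut", "cre"))
Description: Forward-modelling and machine-learning pipeline for non-invasive
    localization of atrial ectopic beats. Generates a synthetic biatrial surface
    model with regional conduction heterogeneity and interatrial connections
    (Bachmann's bundle, fossa ovalis, coronary-sinus bridges), simulates focal
    activation with a monodomain reaction-diffusion solver or an anisotropic
    eikonal surrogate, projects transmembrane sources to a torso lead array
    through an equivalent-dipole volume conductor, computes body-surface P-wave
    integral maps (BSPiM) and related biomarkers, clusters the maps into ectopic
    atrial regions (K-means, EM) and classifies unseen maps with a multiclass
    RBF support vector machine under stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
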