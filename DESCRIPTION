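Package: aneupiv
Title: Stereoscopic Particle Image Velocimetry Assessment of Flow-Diverter
    Efficacy in an Idealized Intracranial Aneurysm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how flow-diverter stent placement alters the
    hemodynamics of an idealized side-wall intracranial aneurysm, using a
    fully synthetic stereoscopic particle image velocimetry (PIV) chain.
    Provides an analytical pulsatile flow phantom with parametric treatment
    scenarios, virtual two-camera particle imaging, multi-pass FFT
    cross-correlation with sub-pixel Gaussian peak fitting and
    normalized-median outlier validation, two-camera three-component
    velocity reconstruction, phase averaging over cardiac cycles, and the
    efficacy metrics used in treatment studies: intra-saccular velocity
    reduction, normalized out-of-plane fluctuation, the oscillatory
    velocity index (OVI), and probe time series. Reads and writes EnSight
    Gold ASCII cases for interchange with deposited experimental datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
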