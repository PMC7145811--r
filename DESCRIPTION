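Package: coraloptics
Title: Photon Transport and Optical Characterization of Photosynthetic
    Biomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward Monte Carlo simulation of light propagation in layered
    and voxelized scattering-absorbing media (Henyey-Greenstein phase
    function, Fresnel interfaces, time-of-flight tracking), inverse
    estimation of optical properties from integrating-sphere transmission
    series and goniometer angular scans (diffusion-slab fitting of the
    transport mean free path and absorption length, extrapolation-length
    estimation, Beer-Lambert extinction, Brewster-angle refractometry),
    conversion of tomographic image stacks into printable surface meshes
    and slice masks, segmentation and shape analysis of algal aggregates
    in confocal volumes, and microsensor-based photosynthesis analysis
    (Fick-law diffusive oxygen flux, light-dark shift rates,
    photosynthesis-irradiance and logistic growth fits). Every analysis is
    exercisable on synthetic phantoms with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    minpack.lm,
    stats,
    withr,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
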