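Package: ablatesim
Title: Transient Laser Ablation Simulation with Dynamic Optical Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional transient simulation of laser tissue ablation.
    Couples voxel-based Monte Carlo photon transport (Henyey-Greenstein
    scattering, Fresnel boundaries, Russian roulette) to an enthalpy-method
    finite-difference heat solver with a latent-heat plateau, Arrhenius
    thermal-damage kinetics, and a dynamic optical properties model that
    updates the reduced scattering coefficient of each voxel as tissue
    coagulates. Vaporized voxels are removed from the lattice to form a
    crater. Includes scenario generators for scanned-beam irradiation of
    liver-like tissue, lesion metrics (coagulation and vaporization width,
    depth and area), and validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
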