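Package: pbsmc
Title: Monte Carlo Dose Engine for Proton Pencil Beam Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo dose calculation platform for proton
    pencil beam scanning (PBS). Provides a parameterized phase-space source
    model commissioned from spot-profile, depth-dose and absolute-dose
    measurements (Courant-Snyder beam optics, Gaussian energy spectrum,
    protons per monitor unit), a condensed-history proton transport engine
    with Bethe stopping power, Highland multiple Coulomb scattering, Bohr
    energy straggling and nonelastic nuclear removal, support for a Lexan
    range shifter and voxelized heterogeneous phantoms, and a dosimetric QA
    suite (field-size factors, spread-out Bragg peak metrics, gamma index,
    dose-volume histograms, radial halo integrals). A virtual-machine fixture
    generator allows the whole commissioning and validation chain to run
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
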