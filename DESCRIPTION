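Package: lipidphonon
Title: Collective Dynamics and Lateral Organization of Cholesterol-Rich
    Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of triple-axis inelastic neutron scattering and
    molecular-configuration data for phospholipid/cholesterol membranes
    perturbed by small amphiphilic drugs such as aspirin. Fits
    constant-q and constant-energy spectra with a detailed-balance
    multi-phonon model, selects the phonon count by a sequential F-test,
    assembles and fits three-branch dispersion relations around their
    minima, reconstructs lamellar scattering-length-density profiles
    from Bragg series with supplied Fourier phases, and computes lateral
    organization observables (per-leaflet radial distribution functions,
    grid-based area per lipid, gauche-defect fractions, density
    profiles, close contacts) from membrane configuration frames.
    Synthetic-data generators with attached ground truth emulate every
    input at realistic instrument and simulation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
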