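Package: memdrug
Title: Drug-Membrane Interaction Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of small-molecule binding at phospholipid bilayer
    membranes from molecular dynamics trajectories: site-site radial
    distribution functions with exact pair-count normalisation, potentials
    of mean force via the reversible-work relation and extraction of
    first-minimum/first-maximum free-energy barriers, area-per-lipid and
    bilayer-thickness time series, and hydrogen-bond lifetime and bridging
    analysis tolerant to transient bond breaking. Includes a synthetic
    trajectory generator that emulates a two-leaflet DOPC/DOPS/cholesterol
    patch with a single drug molecule whose donor sites bind partner
    oxygens with prescribed bond-length distributions and two-state on/off
    kinetics, so every estimator can be validated against known ground
    truth without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
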