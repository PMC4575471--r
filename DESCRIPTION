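Package: dbacsim
Title: Desk-Scale Simulation of an Automated HIFU Hemostasis Cuff
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for a circumferential high-intensity
    focused ultrasound (HIFU) cuff that detects and cauterizes deep arterial
    bleeders in a limb. Generates synthetic limb phantoms with pulsatile
    vascular trees, renders compounded 3D power-Doppler volumes, performs
    automated bleeder detection and localization (vessel segmentation,
    centerline extraction, bifurcation detection, spectral-Doppler resistive
    index classification), selects and power-equalizes therapy-tile groups,
    computes phased-array beam fields and dither-averaged power deposition,
    solves the Pennes bioheat equation with CEM43 thermal dose accounting,
    and closes the loop on both beam targeting (thermal-strain focus
    localization with iterative correction) and dosing (strain-based and
    recurrent-network acoustic thermometry with threshold shut-off).
    Transducer array poses are recovered by time-of-flight multilateration
    through layered media.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
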