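Package: patrus
Title: Desk-Scale Simulation of a Combined Transrectal Ultrasound-Photoacoustic Probe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ray-traced design of a dual-geometry illumination lens
    (concave-convex in the lateral-axial plane, planar-oblique in the
    elevation-axial plane), Monte Carlo photon transport in turbid media,
    convex-array acquisition modelling, and photoacoustic/ultrasound image
    formation on synthetic wire phantoms.  Covers beam characterization
    (field of view, deviation, screen profiles, full width at half maximum),
    fluence prediction for lens versus bare-fiber illumination, band-limited
    pulse synthesis and spectral characterization, walking-aperture
    delay-and-sum beamforming for convex arrays, envelope detection, log
    compression, and sector scan conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
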