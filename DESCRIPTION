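Package: hdrkerma
Title: Photon Monte Carlo Collisional-Kerma Engine for HDR Ir-192 Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A desk-scale photon-only Monte Carlo engine for high-dose-rate
    Ir-192 brachytherapy dosimetry. Transports photons through voxelized
    phantoms (Woodcock delta tracking) with an embedded analytic source
    capsule, scores collisional kerma with a track-length kerma estimator
    and an analogue event-by-event scorer with history-by-history Type A
    uncertainties, characterizes sources in the TG-43 sense (air-kerma
    strength, dose-rate constant, uncertainty budget), drives dwell-time
    weighted treatment-plan sources with phase-space splitting, and reports
    dose-grid comparison metrics and dose-volume histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
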