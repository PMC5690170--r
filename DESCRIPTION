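Package: rcfqa
Title: Transmission Quality Assurance for Radiotherapy with Radiochromic Film
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-vivo transmission quality assurance of radiotherapy
    deliveries using radiochromic film mounted on a tray in the linac
    accessory holder. Converts a scanned film image acquired at
    source-to-detector distance 56.8 cm into an absolute dose plane on the
    isocenter (100 cm) scale via a TPS-anchored calibration, projects,
    denoises, resamples and coregisters it against the planned dose plane,
    compares the two by point-dose difference and gamma analysis
    (dose-difference / distance-to-agreement), and issues a Pass/Fail
    verdict. A synthetic-data module fabricates matched planned doses and
    film scans, including deliveries with injected errors (reduced monitor
    units, removed field), so the whole pipeline can be exercised without
    physical film.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
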