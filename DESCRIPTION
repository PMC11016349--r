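Package: sgrtdynqa
Title: Automated Dynamic Localization Quality Assurance for
    Surface-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automated monthly quality assurance of the dynamic
    localization accuracy of surface-guided radiotherapy (SGRT) systems.
    Builds the couch/gantry motion sequence as a versioned XML control
    script, reads and writes open-dialect linac trajectory logs and
    surface-imaging logs, synchronizes the two time series by first motion,
    averages poses over beam-on time at each couch position, detects a
    radio-opaque ball bearing with sub-pixel accuracy in megavoltage portal
    images and maps projected displacements to isocenter millimetres, and
    reports deviations against AAPM TG-142 stereotactic tolerances
    (1 mm / 1 degree). A built-in session simulator generates trajectory
    logs, surface logs, and MV images with known ground truth so the whole
    pipeline is testable without a linac.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
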