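Package: myographr
Title: Automated Vessel Diameter Tracking for Pressure Myography Image Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measurement core for pressure myography and related vascular
    imaging experiments. Tracks blood vessel inner diameter, outer diameter
    and wall thickness in multipage TIFF time series by locating wall edges
    as sub-pixel peaks in the derivative of intensity profiles sampled along
    user-defined scanlines or arbitrary-angle track lines. Supports
    brightfield, fluorescence, B-mode ultrasound and en-face (flat-mounted)
    preparations, multi-line tracking of branched vessels, pixel-to-micron
    calibration, automated pressure-step protocols run against a simulated
    pressure servo, two-file CSV export with an event log, overlay stacks,
    and a synthetic vessel phantom generator that provides exact ground
    truth for every algorithm.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
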