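Package: flimphasor
Title: Phasor Analysis of TCSPC Fluorescence Lifetime Imaging Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms raw time-correlated single photon counting (TCSPC)
    fluorescence lifetime imaging (FLIM) decay cubes into calibrated phasor
    coordinates and per-pixel phase, modulation and average lifetime maps.
    Reads Becker & Hickl .sdt, PicoQuant .ptu and multi-page TIFF decay
    stacks; supports reference-dye calibration, photon-count thresholds,
    sliding-window pixel binning, manual intensity masks and phasor-space
    region-of-interest selection mapped back to image pixels; pools phasor
    clouds across experimental conditions; exports lifetime maps as float32
    TIFF, per-image summary tables as CSV, and static phasor, map, gallery
    and violin figures. Includes a synthetic TCSPC decay generator with
    known ground truth and a batch command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
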