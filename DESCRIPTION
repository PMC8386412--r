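Package: ringscan
Title: Bootstrap-Consensus Quantification of Radial Growth Patterns on Agar Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies radial growth patterns (central producer spot,
    growth-inhibition valley, outer cheater ring) from photographs of round
    agar plates. Locates the central spot and the plate rim with a circular
    Hough transform, resamples the plate to polar coordinates, and extracts
    feature radii from the derivative of filtered radial intensity profiles.
    Robustness to glare, labels and uneven illumination comes from a
    bootstrap over angular slices: composite polar images are built by
    sampling slices with replacement, candidate feature bounds are collected
    across hundreds of composites, and consensus features are taken as the
    modes of the resulting distributions, converted to millimeters via the
    known plate diameter. Includes a synthetic plate-image generator with
    known ground truth for end-to-end validation, mean-based radial profile
    traces for strain comparisons, and batch CSV/plot outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    digest,
    grDevices,
    graphics,
    jsonlite,
    matrixStats,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
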