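Package: beewaggle
Title: Automatic Detection, Decoding and Mapping of Honey Bee Waggle Dances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects honey bee waggle dances in observation-hive video by
    per-pixel spectral scoring in the 10-16 Hz waggle band, assembles
    activated detectors into waggle runs, filters false positives with a
    compact 3D convolutional network, decodes each run's body orientation
    from accumulated Fourier spectra of difference images, clusters runs
    into dances in space-time, rejects angular outliers with RANSAC and
    projects dances to field coordinates via the solar azimuth. Includes a
    synthetic dance-video renderer with ground-truth logs so the whole
    pipeline can be validated without recorded footage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
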