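Package: surfstain
Title: Multispectral Fluorescence Detection of Invisible Surface Stains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates paired dirty/clean multispectral fluorescence image
    acquisitions of touch surfaces, detects human-eye-invisible stains by
    absolute thresholding and dirty-vs-clean differencing, separates stain
    from background by two-channel and full-cube k-means clustering,
    classifies surfaces dirty/clean with a tile-wise max-margin classifier,
    and benchmarks surface hygiene samples against ATP and total-plate-count
    guideline thresholds with survey aggregation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
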