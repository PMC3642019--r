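Package: vesselct
Title: Synthetic Phase-Contrast CT of Ocular Vasculature and Angiographic
    Score Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates parallel-beam (phase-contrast or absorption) projection
    imaging of branching vessel phantoms, reconstructs axial slices by filtered
    back-projection with rotation-axis estimation and background gray-value
    equalization, segments vessels by block-wise Otsu thresholding over a
    5 x 5 region-of-interest grid followed by morphological opening, and
    quantifies microvessel density via the angiographic score (vessel-pixel
    fraction) together with sub-pixel vessel diameter measurement from
    full-width-at-half-maximum line profiles. Includes group summaries and
    pairwise between-group comparisons of angiographic scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
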