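Package: fibromat
Title: Morphometric Quantification of Liver Fibrosis in Sirius Red Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch morphometry for Sirius Red stained liver sections. Converts
    RGB micrographs to a green-channel grey image, removes slowly varying
    illumination (shading), suppresses pixel noise with an arithmetic mean
    filter, segments the red-stained (green-absorbing) collagen by histogram
    thresholding, separates fibres from similarly stained cell nuclei by
    connected-component area filtering, and reports the fibrosis index: fibre
    area as a fraction of the parenchyma area with bright vessel lumina and
    slide background excluded automatically. Includes a two-tiered
    semi-quantitative fibrosis score (periportal 0-4, perisinusoidal 0-2),
    group summaries (mean with standard error) and score-versus-index linear
    regression, a synthetic stained-field generator with ground-truth masks
    for end-to-end validation, session files for resumable batch work, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
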