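Package: relcolor
Title: Perceptually Linearized Colormaps for Quantitative MR Relaxometry Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, auditing and application of perceptually
    linearized colormaps for displaying quantitative MR relaxometry maps
    (T1, T2, T2* and their rate reciprocals R1, R2, R2*). Builds 256-level
    colormaps from anchor colors by iterative equalization of successive
    CIEDE2000 color differences along a smooth CIELAB path, audits any
    colormap for perceptual uniformity, luminance monotonicity and
    color-vision-deficiency safety, applies linear and logarithm-processed
    value-to-color scaling with an invalid-pixel sentinel, and renders maps
    with a mandatory labelled color bar. Includes a synthetic relaxometry
    phantom generator and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    colorspace,
    jsonlite,
    optparse,
    png,
    RNifti,
    stats,
    utils
Suggests:
    farver,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
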