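Package: chromatrack
Title: Quantifying Background-Matching Colour Change in Amphibian Larvae
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying facultative, melanin-based colour change
    in tadpoles and its morphological and physiological correlates.
    Implements reflectance-spectrum preprocessing (trimming, loess
    smoothing, fixed-width binning) and the colorimetric indices B2
    (brightness), H1 (hue) and S8 (saturation); PCA colour spaces and
    tadpole-background mismatch distances; a three-parameter
    quadratic-plateau model for colour-change kinetics fitted by profile
    least squares; 2D geometric morphometrics (TPS I/O, quadratic
    unbending, generalized Procrustes analysis with sliding semilandmarks,
    permutation Procrustes ANOVA); antioxidant-panel statistics; and Raman
    band-signature classification of eumelanin versus pheomelanin. A
    synthetic-data module generates every input with known ground truth so
    the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
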