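Package: fvcover
Title: Fractional Vegetation Cover Measurement from Nadir RGB Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures fractional vegetation coverage (FVC) from downward-looking
    RGB photographs of herbaceous vegetation. Implements four colour-based
    vegetation segmentation algorithms (ratio/excess-green thresholding, an
    RGB decision tree, the excess-green-minus-excess-red index, and
    excess-green with Otsu thresholding), the FVC statistic, an accuracy
    assessment toolbox (MAPE, BIAS, relBIAS, RMSE, relRMSE, regression and
    analysis of variance against reference coverage), and a synthetic
    vegetation-scene generator with pixel-exact ground truth that emulates
    overcast and sunlit (forenoon/noon) illumination for benchmarking
    algorithm robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
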