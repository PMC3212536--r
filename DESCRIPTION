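Package: dungsurvey
Title: Line-Transect Dung Surveys, Change Inference and Density Surface
    Models for Forest Elephants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for before/after analysis of line-transect dung surveys
    of forest elephants: detection-function fitting (uniform, half-normal,
    hazard-rate) with AIC selection and effective strip width, dung density
    estimation with encounter-rate variance and log-normal confidence
    intervals, two-survey z-tests and chi-square change classification,
    dung-to-elephant and ivory-to-elephant conversions, ordinary kriging of
    density surfaces, Getis-Ord Gi* hotspot detection, landscape covariate
    construction including a composite deforestation index, quasipoisson
    density-surface GAMs with effort offsets and GCV smoothing selection,
    and a synthetic landscape/survey generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
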