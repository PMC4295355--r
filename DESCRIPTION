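Package: pfgbreast
Title: Biexponential PFG-NMR Water Diffusion Analysis of Breast Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for in-vitro pulsed-field-gradient (PFG) NMR diffusion
    analysis of breast tissue specimens. Simulates echo-attenuation decay
    curves for two-phase (fast/slow) water diffusion, decomposes measured
    curves into biexponential components by peel-off stripping with nonlinear
    least-squares refinement, estimates the initial-slope apparent diffusion
    coefficient, relates diffusion parameters to six-part histological
    composition through second-order response-surface regression, and scores
    specimen malignancy with published quadratic cancer-probability models.
    Includes a synthetic-cohort generator calibrated to published group
    statistics so the full pipeline is testable without access to raw
    specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
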