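Package: drsmargin
Title: Quantitative Diffuse Reflectance Spectroscopy for Breast Tumor
    Margin Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward Monte Carlo simulation of fiber-probe diffuse
    reflectance from breast tissue, inverse extraction of chromophore
    concentrations (oxy- and deoxy-hemoglobin, beta-carotene, patent blue
    dye) and reduced scattering via bounded least squares, a factorial
    robustness study of endpoint extraction under sentinel-node blue dye,
    and longitudinal mixed-effects analysis of post-excision endpoint
    kinetics (percent-change statistics, cautery and tissue-type
    comparisons), driven by a seeded synthetic-cohort generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    lme4,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
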