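Package: tmfkit
Title: Trophic Magnification Factors for Biota Monitoring and Quality
    Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines, quality-screens, selects, and applies trophic
    magnification factors (TMFs) for contaminants in aquatic food webs.
    Estimates TMFs by regression of log-transformed, lipid- or dry
    weight-normalized concentrations on stable nitrogen isotope derived
    trophic levels, with mixed-effects and left-censored likelihood
    options for unbalanced or nondetect-rich designs.  Encodes a
    decision tree for screening published TMF studies against quality
    criteria, tiering them by ecosystem and species similarity, pooling
    accepted values by geometric mean, and falling back to
    biomagnification factors, bioconcentration-derived
    biotransformation rates, or a steady-state food-web mass-balance
    model when no field TMF exists.  Standardizes biota monitoring data
    to a reference trophic level and tissue basis for comparison
    against Environmental Quality Standards, and quantifies the
    statistical power of food-web sampling designs to detect trophic
    magnification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
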