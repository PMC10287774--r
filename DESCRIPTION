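Package: mangroveoc
Title: Estimating Mangrove Soil Organic Carbon from Loss-on-Ignition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating soil organic carbon (OC) content of
    mangrove soils from loss-on-ignition (LOI) measurements of soil
    organic matter (SOM).  Ships a registry of published SOM-to-OC
    conversion equations (regional, coastal-environmental-setting,
    sedimentary, general, and literature equations), a hierarchical
    equation-selection rule, two-stage outlier screening (OC:SOM ratio
    bounds and an iterative modified Thompson tau test), regression
    fitting of the linear, quadratic, and power conversion forms,
    residual-based equation validation with a Shapiro-Wilk gated
    t-test/Wilcoxon procedure, sedimentary and coastal-setting group
    comparisons, sequential-LOI carbonate quantification, depth-integrated
    soil carbon stock computation, and a seeded generator of synthetic
    soil-core datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
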