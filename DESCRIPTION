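Package: terravalue
Title: Natural-Attribute Farmland Quality Grading and Economic Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grid-based farmland quality evaluation and economic valuation
    from natural attributes. Converts raw indicator rasters to fuzzy
    membership scores, combines them with analytic-hierarchy-process (AHP)
    weights into a comprehensive farmland quality index per evaluation
    unit, classifies units into quality grades by exact Jenks natural
    breaks, computes climatic production potential with the Thornthwaite
    Memorial model, corrects it by the quality index to obtain
    grade-standard yields, and prices the result into per-grade and total
    economic values. Includes a seeded synthetic-landscape generator
    (autocorrelated indicator fields, categorical patch maps, overlay
    evaluation units) so the full pipeline runs end to end without any
    external data, plus the reference case-study constants for Hefei,
    China as bundled fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
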