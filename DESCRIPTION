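Package: dfva
Title: Differential Flux Variability Analysis with Metabolomics-Constrained
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling pipeline for calling
    condition-specific changes in feasible flux ranges. Implements flux
    balance analysis (FBA), parsimonious FBA, and loopless flux variability
    analysis (FVA) with biomass-fraction and total-flux constraints on a
    bundled linear-programming kernel; derives per-condition metabolite
    abundance ratios from targeted-metabolomics tables; scales
    exchange-reaction bounds by reference pFBA flux times abundance ratio to
    obtain condition-parameterized models; and reports per-reaction altered
    flux calls with pathway-level (glycolysis, pentose phosphate pathway,
    TCA cycle) roll-ups. Ships a hand-analyzable central-carbon toy model, a
    synthetic targeted-metabolomics generator with known ground truth, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
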