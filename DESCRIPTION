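Package: ecomult
Title: Ecological and Economic Ecosystem Multifunctionality for Split-Plot
    Agro-Experiments
Version: 0.1.0
Authors@R:
    person("GCEF", "Analysis Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compute ecological and economic ecosystem
    multifunctionality indices for two-factor (climate x land-use)
    split-plot agricultural field experiments. Provides composite
    ecosystem-function indicators (min-max normalization, Shannon
    diversity, soil multidiversity, soil health, decomposition and
    microbial-biomass conversions, nitrogen surplus bookkeeping),
    stakeholder-weighted ecological multifunctionality, monetized economic
    multifunctionality including a natural-insurance valuation of soil
    biodiversity and soil health via risk premia under lognormal yields,
    an RGB-threshold flower-cover image classifier, split-plot ANOVA with
    Tukey post-hoc comparisons, and a synthetic-data generator emulating
    the experimental design so that every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    jpeg,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
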