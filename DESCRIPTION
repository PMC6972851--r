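Package: beetoxload
Title: County-Level Bee Toxic Load from Insecticide Use, Land Use and
    Honey Bee Toxicity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes county-level annual 'bee toxic load' (honey bee lethal
    doses, contact and oral) from insecticide application weights and
    consensus acute LD50 values, and decomposes it into extent (area treated)
    and intensity (application rate x potency) components. Provides a tiered
    consensus procedure for raw honey-bee toxicity records, linear
    interpolation of missing county-years, census-cell imputation,
    Mann-Kendall trend tests with tie correction, response-ratio fold
    changes, hierarchical time-series clustering of regional load
    trajectories (Euclidean distance, Ward linkage), Fisher-Jenks natural
    breaks classification including a zero-centered variant for change maps,
    and a synthetic-data generator with planted ground truth that emulates
    the public pesticide-use, agricultural-census and toxicity source tables
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
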