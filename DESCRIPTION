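Package: eatr
Title: Task-Based Soil Exposure Dose Modelling with the EAT-R Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates agricultural workers' average daily doses of soil
    contaminants via incidental ingestion and dermal contact at the
    meso-activity (task) level. Scenario grids decompose exposure by task,
    season, environment and receptor using the Environment, Activity,
    Timing - Receptor (EAT-R) factor taxonomy; a stepwise sensitivity
    cascade quantifies how each factor class shifts dose estimates relative
    to a traditional single-scenario model. Includes a seeded scenario
    generator, YAML/JSON scenario configuration with a published schema,
    tabular dose reports, and broom-style tidiers with ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
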