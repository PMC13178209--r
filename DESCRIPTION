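Package: farmsoc
Title: Farm Management Effects on Soil Organic Carbon from Linked Survey and
    Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links farm-survey microdata to soil-monitoring points to quantify
    how agricultural management shapes soil organic carbon (SOC) at continental
    scale. Provides a seeded synthetic-data generator with known ground truth,
    per-farm management indicators (nutrient input, manure share, rotation
    diversity and composition, tillage intensity), tiered spatial
    disaggregation of management to monitoring points via area-based weighted
    medians, three SOC metrics (0-20 cm stocks from a reference bulk density
    selected by exhaustive AIC search, benchmark ratios against pedoclimatic
    typical stocks, and yearly change in SOC concentration), a rank-based
    management-intensity composite, linear mixed models with backward
    elimination and marginal effects, and best/worst-decile management
    scenarios upscaled to total carbon with propagated uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    ranger,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
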