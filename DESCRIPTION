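Package: cuptox
Title: Acute Copper Toxicity Analysis for Hard Dryland River Waters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational chain of an acute copper toxicity
    bioassay in natural river water: probit dose-response fitting with LC50
    (and general LCp) estimation and confidence intervals at each observation
    time, an exponential LC50-versus-time decay model, US EPA water-hardness
    normalization of LC50s for cross-study comparison, copper solid/solution
    partitioning (particulate Cu and the Kd partition coefficient), and
    dry/wet-season comparison of hydrochemistry via a bootstrap-standardized
    difference-of-means (dm) statistic. A synthetic-data generator reproduces
    the statistical structure of the survival trials and seasonal monitoring
    series so the whole pipeline is testable without access to raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
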