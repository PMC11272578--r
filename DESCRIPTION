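Package: mrpipe
Title: Two-Sample Mendelian Randomization Pipelines for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and harmonizing exposure and outcome association
    tables onto a shared effect allele, selecting instrumental variables by
    p-value threshold, LD clumping, F-statistic filtering and confounder
    blacklists, estimating causal effects with inverse-variance-weighted,
    MR-Egger, weighted-median and mode-based estimators, and running the
    standard sensitivity suite (Cochran's Q, Egger intercept, MR-PRESSO
    outlier search, leave-one-out). Includes a synthetic summary-statistic
    generator with known causal structure for calibration and power studies,
    and a scan driver for many exposures against one outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
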