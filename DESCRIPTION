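Package: dipa
Title: Detroit Interventional Pain Assessment (DIPA) Scoring and Reporting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-operative pain-management assessment with the
    Detroit Interventional Pain Assessment (DIPA) scale. Converts prescription
    records to daily morphine milligram equivalents (MME) with a versioned
    opioid conversion-factor table, assigns the five-level A-E medication
    class (operational cutoffs or boundaries derived by hierarchical and
    K-means clustering), combines the class with the three-level
    Interventional Pain Assessment (IPA) pain score into a DIPA rating,
    aggregates cohorts into per-period provider efficiency scores, runs a
    nonparametric validation battery (Shapiro-Wilk, Kruskal-Wallis,
    Mann-Whitney with exact small-sample enumeration, Spearman rank
    correlation), generates seeded synthetic cohorts for pipeline testing,
    and renders longitudinal DIPA graphs and class boxplots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
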