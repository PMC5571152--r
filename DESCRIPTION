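Package: ricemeta
Title: Replicate-Weighted Meta-Analysis of Rice Tillage and Crop-Establishment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing alternative rice tillage and crop-establishment
    options against the puddled-transplanted control across many independent
    field studies. Implements log response-ratio effect sizes with
    replicate-based weights, within-study weight division, a 3-SD outlier
    screen, categorical random-effects pooling with a generalized
    DerSimonian-Laird between-study variance, bias-corrected bootstrap
    confidence intervals, and back-transformation to percent change; a
    parallel study-random-effect linear mixed model with least-squares means,
    all-pairwise comparisons and a compact letter display for unbalanced data;
    a synthetic multi-study corpus generator with serialized ground truth for
    parameter-recovery testing; and pipeline commands that tie the stages into
    reproducible analysis runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    emmeans,
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
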