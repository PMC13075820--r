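Package: hostresist
Title: Heritability of Parasitism Resistance and Its Life-History Costs in a Haplodiploid Pest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of parasitoid resistance in
    haplodiploid insects from family-level survival assays: a synthetic-data
    generator emulating a paired full-sib/half-sib breeding design with
    binomial survival outcomes, EM-based restricted maximum likelihood (REML)
    estimation of dam, sire, block, plant and residual variance components,
    conversion to haplodiploid-adjusted narrow-sense heritability, a
    penalized-quasi-likelihood binomial mixed model for treatment effects, and
    life-history cost analyses (negative-binomial fecundity models,
    beta-binomial hatch-success models, likelihood-ratio tests, and exact
    binomial confidence intervals), with a reproducible simulate-estimate-report
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nlme,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    glmmTMB,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
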