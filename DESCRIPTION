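Package: mutaccum
Title: Mutation Accumulation Line Analysis Across Seasonal Environments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating mutation parameters from mutation
    accumulation (MA) line field experiments. Simulates phenotype data
    with the hierarchical block/line/field-subline design and seasonal
    variance structure typical of MA assays, fits variance-component
    generalized linear mixed models by maximum likelihood (via lme4) and
    by Markov chain Monte Carlo, selects random effects with parametric
    bootstrap likelihood-ratio tests, and transforms among-line variance
    into per-generation mutational variance (V_m), mutational
    heritability (h2_m), and the mutational coefficient of variation
    (CV_m) with posterior credible intervals, plus founder-versus-MA
    mean comparisons by paired t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
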