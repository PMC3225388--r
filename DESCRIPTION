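Package: collapsim
Title: Non-Collapsibility of the Odds Ratio in Single-SNP Case-Control
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates dichotomous disease under a multi-locus logistic
    (odds) penetrance model and quantifies how single-SNP association
    analysis underestimates conditional odds ratios because the odds
    ratio is a non-collapsible effect measure.  Provides exact
    calibration of the model intercept to a target prevalence, the
    closed-form genotype distribution of a focal SNP given disease
    status, an analytic asymptotic marginal odds ratio, Monte-Carlo
    case-control cohort simulators for both an equal-effects and a
    heterogeneous (exponential effect sizes, uniform allele
    frequencies) genetic architecture, McKelvey-Zavoina explained
    variance on the log-odds scale, and grid experiments over
    prevalence, allele frequency and number of risk SNPs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
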