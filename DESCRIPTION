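Package: metanova
Title: Per-Metabolite Mixed-Model ANOVA for Factorial Metabolomics Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a linear mixed model with a nested random effect to every
    metabolite of a wide-format feature table, runs Kenward-Roger adjusted
    Type III two-way (or one-way) ANOVA, computes back-transformed least
    squares means with confidence intervals and Tukey-Kramer or Bonferroni
    adjusted pairwise comparisons, tests residual normality, corrects ANOVA
    p-values across metabolites by false discovery rate or Bonferroni, and
    consolidates all results into a single sortable table. Includes a
    synthetic-data generator that reproduces the assumed design structure
    (two crossed treatments, pens nested in treatment cells, animals within
    pens) for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    nortest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
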