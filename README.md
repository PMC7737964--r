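# metanova

Per-metabolite mixed-model ANOVA for factorial metabolomics studies.

Untargeted metabolomics assays routinely report hundreds of metabolite peak
areas per study, and animal experiments behind them often have a factorial
treatment structure with a hierarchical design: animals housed in pens, pens
nested in the treatment combinations. Analysing such data one metabolite at a
time requires a linear **mixed** model — a plain two-way ANOVA ignores the
within-pen correlation — plus multiplicity control both *within* a metabolite
(pairwise comparisons) and *across* metabolites (hundreds of simultaneous
ANOVAs). `metanova` automates that workflow and consolidates the results into
a single sortable table.

## The model

For each metabolite, the response (optionally log- or square-root-transformed)
is modelled as

```
y_ijkl = mu + alpha_k + gamma_l + (alpha*gamma)_kl + b_j(kl) + e_ijkl
```

where `alpha_k` and `gamma_l` are the fixed effects of the two treatments,
`(alpha*gamma)_kl` their interaction, `b_j(kl) ~ N(0, sigma2_pen)` the random
effect of pen `j` nested in treatment cell `(k, l)`, and
`e_ijkl ~ N(0, sigma2_e)` the residual. Per metabolite, the pipeline

1. fits the model by REML (sum-to-zero contrasts),
2. runs Type III F tests with Kenward-Roger denominator degrees of freedom,
3. computes least squares means (margins and cells) with confidence
   intervals, back-transformed to the original scale,
4. computes all pairwise LSmean differences with raw p-values and
   Tukey-Kramer (or Bonferroni) adjusted p-values,
5. tests residual normality (Shapiro-Wilk and Lilliefors/Kolmogorov-Smirnov),

then adjusts the ANOVA p-values **across metabolites** per effect by the
Benjamini-Hochberg FDR (or Bonferroni), and writes one consolidated row per
metabolite, sorted by the first treatment factor's raw p-value. A metabolite
whose fit fails (empty cell, transform domain error, non-convergence) stays
in the table as a flagged row; it never aborts the run.

## Worked example

Simulate a study shaped like a 26-animal, 2×2 feeding trial (pens of paired
animals, 4/3/4/3 pens per cell) where the last three of twelve metabolites
carry a diet effect of 1.2 on the log scale, then analyse it:

```r
library(metanova)
ft <- simulate_feature_table(feeding_trial_design(
  n_metabolites = 12, seed = 2026,
  effect_factor2 = c(rep(0, 9), 1.2, 1.2, 1.2)
))
res <- run_two_way(ft, "Trx1", "Trx2", random_unit = "pen")
res
#> metanova_result: 12 metabolites x 26 samples; 12 fits ok (5 boundary), 0 failed
#>   transformation: log; across-metabolite adjustment: fdr
#>  Response Pvalue_Trx1 AdjPvalue_Trx1      Status
#>    met002  0.04196069      0.5035282 ok_boundary
#>    met009  0.13604636      0.6356599          ok
#>    met005  0.23624312      0.6356599 ok_boundary
#>    met012  0.26366529      0.6356599          ok
#>    met003  0.26485829      0.6356599          ok
```

The diet (`Trx2`) columns pick out exactly the three planted effects after
FDR adjustment:

```r
tab <- res$table
head(tab[order(tab$Pvalue_Trx2),
         c("Response", "Pvalue_Trx2", "AdjPvalue_Trx2", "LS_CON", "LS_HFF")], 5)
#>  Response Pvalue_Trx2 AdjPvalue_Trx2 LS_CON LS_HFF
#>    met010    0.000559        0.00671  11024  36950
#>    met012    0.001953        0.01172  13740  45181
#>    met011    0.003012        0.01205  14610  31402
#>    met007    0.066516        0.19955  26819  19385
#>    met003    0.146093        0.35032  17157  24210
```

`Pvalue_Trx2` is the Kenward-Roger Type III p-value for diet,
`AdjPvalue_Trx2` its BH-FDR adjustment across the 12 metabolites, and
`LS_CON`/`LS_HFF` are the diet-margin least squares means back-transformed to
peak-area scale (the generator's grand mean is e^10 ≈ 22,000). For 2-level
factors the raw marginal pairwise p-value (`P_valueD_Trx2_CON_HFF`) equals
the ANOVA p-value, and Tukey-Kramer with two means leaves it unchanged —
both identities are enforced by the test suite.

Real data enter through `read_wide_table()` / `run_two_way(input = "file.csv",
...)`: a wide CSV with one row per sample, design columns (treatments, pen,
animal id), and one column per metabolite, missing peaks encoded as `.`.
`run_one_way()` handles single-factor designs, and `exec/metanova` exposes
`twoway`, `oneway` and `simulate` subcommands for shell use.

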