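---
title: "Methods: per-metabolite mixed-model ANOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-metabolite mixed-model ANOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistical problem

Untargeted metabolomics studies of designed animal experiments produce a
wide table: one row per animal, one column per metabolite peak area, plus
design columns. The experiments we target have a 2×2 factorial treatment
structure with animals housed in pens and pens nested inside the treatment
cells. Animals in the same pen share feed access, microbial exposure and
handling, so their measurements are positively correlated; a model without
the pen term understates the standard errors of every treatment contrast and
inflates the type-I error of the between-pen effects. `metanova` fits, for
every metabolite separately,

$$y_{ijkl} = \mu + \alpha_k + \gamma_l + (\alpha\gamma)_{kl}
           + b_{j(kl)} + e_{ijkl},$$

with fixed treatment effects $\alpha_k$, $\gamma_l$, their interaction, a
pen random effect $b_{j(kl)} \sim N(0, \sigma^2_{pen})$ iid across pens, and
residual $e_{ijkl} \sim N(0, \sigma^2_e)$. A single random intercept with
iid structure is the standard choice for one nested grouping factor; more
elaborate covariance structures (repeated measures, AR(1)) are out of scope.

## Estimation and inference

**REML.** Variance components are estimated by restricted maximum
likelihood, which removes the downward bias maximum likelihood incurs from
estimating the fixed effects. The fit is delegated to `lme4`/`lmerTest`, the
canonical mixed-model machinery in R, behind the package's own
`fit_metabolite()` surface; the test suite checks the estimates against the
closed-form nested-ANOVA estimators on balanced designs (within-pen mean
square; pen mean square minus within, divided by pen size) and against a
dense-algebra REML likelihood evaluated on a grid. The boundary estimate
$\hat\sigma^2_{pen} = 0$ is legitimate and occurs with positive probability
when the true pen variance is small; such fits are flagged `ok_boundary` in
the `Status` column but are reported in full.

**Type III tests with Kenward-Roger df.** All fixed terms use sum-to-zero
contrasts, under which the Wald block test of each term adjusted for all
others equals the classical Type III test whenever every factorial cell is
filled. Small samples (here: 26 animals in 14 pens) make the asymptotic
Wald distribution unreliable for between-pen effects, so denominator degrees
of freedom and the fixed-effect covariance use the Kenward-Roger adjustment
(via `pbkrtest`, reached through `lmerTest::anova`). In balanced designs this
reproduces the classical split-plot test exactly: denominator df equal pens
minus cells, a property the suite asserts. If the Kenward-Roger computation
fails (singular information matrix), the pipeline falls back to
Satterthwaite with a classed warning; in balanced designs the two coincide.

**LSmeans and pairwise comparisons.** Least squares means are linear
combinations of the fixed effects that average evenly over the other
factor's levels; both treatment margins *and* the four cell means are
reported, since follow-up questions concern either main effects or simple
effects. Confidence intervals use the Kenward-Roger variance and df per
estimate, and all quantities are back-transformed to the original
measurement scale for reporting (the maps are monotone, so interval
endpoints transform directly). Pairwise differences within a family (a
margin or the cells) carry a raw two-sided t p-value and an adjusted one:

* **Tukey-Kramer** refers $\sqrt{2}\,|t|$ to the studentized range with $k$
  equal to the number of means in the family. With $k = 2$ it reduces
  exactly to the raw t test.
* **Bonferroni** multiplies by the number of comparisons actually made.
  Tukey-Kramer over all $\binom{4}{2} = 6$ cell comparisons overpenalizes
  when only a few simple effects are of interest, so the cell family can be
  restricted (`cell_pairs`) and the Bonferroni multiplier then follows the
  restricted count.

The studentized-range tail probability is `stats::ptukey`; the contrast
estimates, standard errors and per-contrast df come from `emmeans`.

## Multiplicity across metabolites

Each effect's ANOVA p-values form one family across metabolites (so a
218-metabolite run has three families of up to 218). Adjustment is
Benjamini-Hochberg FDR by default, Bonferroni optionally, through
`stats::p.adjust`; metabolites whose fit failed contribute `NA` and are
excluded from the family size, mirroring how SAS's multiple-testing
procedure treats missing p-values. Adjusting per effect rather than pooling
all three effects into one family matches the consolidated table layout in
which every effect carries its own adjusted column.

## Transformations and diagnostics

One transformation code applies to the whole run: none, natural log
(default), or square root. The log is the natural log; since the
back-transformation inverts the same function, the choice of base does not
affect any reported value on the original scale. Per-metabolite
transformation decisions are deliberately left to the analyst: inspect the
normality output, transform the offending columns in the input, and rerun
with code 0. Box-Cox selection is out of scope.

Normality is tested on the *marginal* residuals $y - X\hat\beta$ (random
effects not subtracted), matching how the diagnostic is defined in the
mixed-procedure output this workflow descends from. Two tests are reported:
Shapiro-Wilk, and Lilliefors' Kolmogorov-Smirnov variant — appropriate
because location and scale are estimated — whose reported p-value is capped
at 0.15, the convention of its tabulated approximation (the uncapped value
is kept internally). QQ plot data use Blom plotting positions
$(i - 3/8)/(n + 1/4)$.

## Missing data and degenerate inputs

Missing peak areas (`.` in the CSV) are deleted casewise per metabolite.
After deletion the model frame is checked: at least two observed levels per
factor, no empty factorial cell, at least as many pens as cells. Violations,
transform domain errors (nonpositive value under log), and non-convergence
are contained per metabolite: the consolidated row keeps its place with
`NA` fields and a reason code in `Status`. Failed rows sort last (ties in
p-values keep input order). With the random term absent the model reduces to
OLS and the classical residual df apply.

## The synthetic-data generator

`sim_design()`/`simulate_feature_table()` generate tables with exactly the
structure the model assumes: crossed treatments, pens nested in cells,
animals within pens, log-normal intensities. `feeding_trial_design()` fixes the
design at a typical 2×2 feeding trial: 4/3/4/3 pens per cell, paired
housing, 26 assayed samples (8/5/8/5 per cell), 218 metabolites. Defaults
chosen once as realistic for normalized peak areas: grand mean 10 on the log
scale (≈ 2×10⁴ on peak-area scale), $\sigma^2_{pen} = 0.05$ and
$\sigma^2_e = 0.2$ on the log scale — residual CV around 50% with pens
contributing a fifth of the variance — and zero treatment effects unless
requested. Effect sizes are log-scale differences between levels;
missingness is inserted completely at random at a configurable rate.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: correlation between metabolites (each column
is drawn independently, as the per-metabolite model itself assumes),
heavy-tailed or zero-inflated intensity distributions, and
detection-limit-driven (not-at-random) missingness. Conclusions about FDR
behaviour under strong inter-metabolite correlation in particular do not
follow from these simulations.

## Problem sizes used in the simulation tests

Monte-Carlo checks run at sizes chosen to give informative error bars while
keeping the suite fast: null calibration uses 3 replicates of a
200-metabolite study (600 p-values per effect; the binomial 99% band at
n = 600 is ±2.3 percentage points around 0.05), BH false-discovery
behaviour is assessed over the 9 resulting effect families, and
variance-component recovery uses 40 metabolites on a 60-pens-per-cell
balanced design, where the sampling error of the pen-variance estimator is
roughly 13%, so a 25% accuracy band should hold for ~95% of draws.

## Known limitations

* Two crossed fixed factors at most; no covariates, three-way designs, or
  repeated measures.
* One nested random term with iid structure; no AR(1)/unstructured
  covariance.
* The preliminary multivariate screen (PERMANOVA, PCA) that typically
  precedes per-metabolite modelling is separate work for other tools.
* Transformation is global per run; per-metabolite transformation requires
  editing the input and rerunning untransformed.
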