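#' Across-metabolite p-value adjustment
#'
#' When the same effect is tested once per metabolite, its p-values form one
#' family whose size is the number of metabolites successfully tested.
#' `adjust_bh()` applies the Benjamini-Hochberg step-up false discovery rate
#' adjustment; `adjust_bonferroni()` the Bonferroni bound. Missing p-values
#' (failed fits) stay missing and do not count towards the family size.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return vector of adjusted p-values, same length and `NA` pattern.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' adjust_bonferroni(c(0.01, 0.4))
#' @export
adjust_bh <- function(pvals) {
  check_pvalues(pvals)
  stats::p.adjust(pvals, method = "BH")
}

#' @rdname adjust_bh
#' @export
adjust_bonferroni <- function(pvals) {
  check_pvalues(pvals)
  stats::p.adjust(pvals, method = "bonferroni")
}

check_pvalues <- function(pvals) {
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1)
  if (any(bad)) {
    mn_error("invalid_pvalue",
             sprintf("p-values outside [0, 1] at position(s) %s",
                     paste(which(bad), collapse = ", ")))
  }
  invisible(pvals)
}

#' @rdname adjust_bh
#' @param method `"fdr"` (Benjamini-Hochberg) or `"bonferroni"`.
#' @export
adjust_pvalues <- function(pvals, method = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  if (method == "fdr") adjust_bh(pvals) else adjust_bonferroni(pvals)
}

#' Adjust ANOVA p-values within each effect family
#'
#' Applies the across-metabolite adjustment separately for each tested
#' effect (first treatment, second treatment, interaction), matching the
#' consolidated table's per-effect adjusted columns.
#'
#' @param tests data.frame with columns `response`, `effect`, `p_raw` (one
#'   row per metabolite and effect).
#' @param method `"fdr"` or `"bonferroni"`.
#' @return the input with a `p_adjusted` column added.
#' @export
adjust_all_effects <- function(tests, method = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(c("response", "effect", "p_raw") %in% names(tests)))
  tests$p_adjusted <- NA_real_
  for (eff in unique(tests$effect)) {
    i <- tests$effect == eff
    tests$p_adjusted[i] <- adjust_pvalues(tests$p_raw[i], method)
  }
  tests
}
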