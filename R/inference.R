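#' Type III tests of the fixed effects
#'
#' Tests each fixed effect (both treatments and, if present, their
#' interaction) adjusted for all other model terms. With the sum-to-zero
#' contrasts set by [fit_metabolite()] and all factorial cells filled, the
#' Wald block test computed here coincides with the classical Type III test.
#' For mixed fits the denominator degrees of freedom use the Kenward-Roger
#' small-sample adjustment (or Satterthwaite when requested, or as a
#' fallback when the Kenward-Roger information matrix is singular); for
#' fixed-effects-only fits the usual residual degrees of freedom apply.
#'
#' @param fit a [fit_metabolite()] result.
#' @return a data.frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_den`, `p_raw`. Row order: factor1, factor2, interaction.
#' @export
type3_anova <- function(fit) {
  stopifnot(inherits(fit, "metabolite_fit"))
  spec <- fit$spec
  effects <- c(spec$factor1, spec$factor2,
               if (spec$interaction) paste(spec$factor1, spec$factor2, sep = ":"))

  if (inherits(fit$model, "lmerMod")) {
    ddf <- if (spec$ddf_method == "kenward-roger") "Kenward-Roger" else "Satterthwaite"
    a <- tryCatch(
      suppressMessages(stats::anova(fit$model, type = 3, ddf = ddf)),
      error = function(e) {
        mn_warn("kr_fallback",
                sprintf("Kenward-Roger failed (%s); using Satterthwaite",
                        conditionMessage(e)))
        suppressMessages(stats::anova(fit$model, type = 3, ddf = "Satterthwaite"))
      }
    )
    out <- data.frame(
      effect = rownames(a),
      F = a[["F value"]],
      df_num = a[["NumDF"]],
      df_den = a[["DenDF"]],
      p_raw = a[["Pr(>F)"]],
      stringsAsFactors = FALSE
    )
  } else {
    a <- stats::drop1(fit$model, scope = ~., test = "F")
    a <- a[rownames(a) != "<none>", , drop = FALSE]
    out <- data.frame(
      effect = rownames(a),
      F = a[["F value"]],
      df_num = a[["Df"]],
      df_den = stats::df.residual(fit$model),
      p_raw = a[["Pr(>F)"]],
      stringsAsFactors = FALSE
    )
  }
  out <- out[match(effects, out$effect), , drop = FALSE]
  out$effect <- effects
  rownames(out) <- NULL
  out
}
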