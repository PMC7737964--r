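# LSmeans and pairwise comparisons, built on emmeans reference grids.
# Kenward-Roger df are computed per estimate/contrast for mixed fits.

emm_grid <- function(fit, scope = c("factor1", "factor2", "cells")) {
  scope <- match.arg(scope)
  spec <- fit$spec
  vars <- switch(scope,
    factor1 = spec$factor1,
    factor2 = {
      if (is.null(spec$factor2)) mn_error("invalid_scope", "model has no second factor")
      spec$factor2
    },
    cells = {
      if (is.null(spec$factor2)) mn_error("invalid_scope", "model has no second factor")
      c(spec$factor1, spec$factor2)
    }
  )
  specs <- stats::as.formula(paste("~", paste(vars, collapse = "*")))
  args <- list(object = fit$model, specs = specs, data = fit$frame)
  if (inherits(fit$model, "lmerMod")) {
    args$lmer.df <- if (fit$spec$ddf_method == "kenward-roger") "kenward-roger"
                    else "satterthwaite"
  }
  # emmeans notes that margins average over an interaction; that averaging
  # is exactly the LSmean definition used here, so the note is muffled.
  emm <- suppressMessages(do.call(emmeans::emmeans, args))
  list(emm = emm, vars = vars)
}

cell_labels <- function(grid_df, vars) {
  apply(grid_df[, vars, drop = FALSE], 1L, paste, collapse = "_")
}

#' Least squares means with confidence intervals
#'
#' Model-based (estimated marginal) means for one treatment margin or for
#' the factorial cells, averaging evenly over the other factor's levels.
#' Standard errors use the Kenward-Roger adjusted covariance for mixed fits,
#' and confidence limits use the matching degrees of freedom. Estimates and
#' limits are reported both on the analysis scale and back-transformed to
#' the original measurement scale.
#'
#' @param fit a [fit_metabolite()] result.
#' @param scope `"factor1"`, `"factor2"` (margins) or `"cells"`.
#' @param level confidence level.
#' @return a data.frame with `scope`, `label`, one column per grid factor,
#'   `estimate`, `se`, `df`, `lower`, `upper` (analysis scale) and
#'   `bt_estimate`, `bt_lower`, `bt_upper` (original scale).
#' @export
ls_means <- function(fit, scope = c("factor1", "factor2", "cells"), level = 0.95) {
  stopifnot(inherits(fit, "metabolite_fit"))
  scope <- match.arg(scope)
  g <- emm_grid(fit, scope)
  s <- summary(g$emm, infer = c(TRUE, FALSE), level = level)
  s <- as.data.frame(s)
  bt <- back_transform_interval(s$emmean, s$lower.CL, s$upper.CL, fit$spec$transform)
  out <- data.frame(
    scope = scope,
    label = cell_labels(s, g$vars),
    s[, g$vars, drop = FALSE],
    estimate = s$emmean,
    se = s$SE,
    df = s$df,
    lower = s$lower.CL,
    upper = s$upper.CL,
    bt_estimate = bt$estimate,
    bt_lower = bt$lower,
    bt_upper = bt$upper,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pairwise comparisons of least squares means
#'
#' All pairwise differences within a family of means (a treatment margin or
#' the factorial cells), with the raw two-sided t p-value and a
#' multiplicity-adjusted p-value. Tukey-Kramer adjustment refers
#' \eqn{\sqrt{2}\,|t|} to the studentized range with \eqn{k} = number of
#' means in the (possibly restricted) family; Bonferroni multiplies by the
#' number of comparisons actually made. Degrees of freedom are computed per
#' contrast (Kenward-Roger for mixed fits).
#'
#' Tukey-Kramer is the appropriate choice for marginal (main-effect)
#' comparisons; for simple-effect comparisons among cell means it quickly
#' overpenalizes, and a Bonferroni adjustment sized by the comparisons of
#' interest (via `pairs_filter`) is recommended instead.
#'
#' @param fit a [fit_metabolite()] result.
#' @param family `"factor1"`, `"factor2"` or `"cells"`.
#' @param method `"tukey"` (Tukey-Kramer) or `"bonferroni"`.
#' @param pairs_filter optional character vector restricting the cells family
#'   to named comparisons, each `"<labelA> vs <labelB>"` with cell labels
#'   `<level1>_<level2>` (order within a pair irrelevant).
#' @return a data.frame with `family`, `label_a`, `label_b`, `diff`, `se`,
#'   `df`, `t`, `p_raw`, `p_adjusted`, `method`.
#' @export
pairwise_comparisons <- function(fit, family = c("factor1", "factor2", "cells"),
                                 method = c("tukey", "bonferroni"),
                                 pairs_filter = NULL) {
  stopifnot(inherits(fit, "metabolite_fit"))
  family <- match.arg(family)
  method <- match.arg(method)
  g <- emm_grid(fit, family)
  grid_df <- as.data.frame(summary(g$emm))
  labels <- cell_labels(grid_df, g$vars)
  k_all <- length(labels)
  if (k_all < 2L) mn_error("invalid_scope", "pairwise family needs at least 2 means")

  idx <- utils::combn(k_all, 2L)
  pair_names <- paste(labels[idx[1L, ]], labels[idx[2L, ]], sep = " vs ")
  keep <- rep(TRUE, ncol(idx))
  if (!is.null(pairs_filter)) {
    if (family != "cells") {
      mn_error("invalid_filter", "pairs_filter applies to the cells family only")
    }
    rev_names <- paste(labels[idx[2L, ]], labels[idx[1L, ]], sep = " vs ")
    keep <- pair_names %in% pairs_filter | rev_names %in% pairs_filter
    if (!any(keep)) mn_error("invalid_filter", "pairs_filter matched no comparison")
  }
  idx <- idx[, keep, drop = FALSE]

  cons <- lapply(seq_len(ncol(idx)), function(j) {
    v <- numeric(k_all)
    v[idx[1L, j]] <- 1
    v[idx[2L, j]] <- -1
    v
  })
  names(cons) <- pair_names[keep]
  ct <- as.data.frame(summary(emmeans::contrast(g$emm, cons), adjust = "none"))

  t_stat <- ct$t.ratio
  p_raw <- ct$p.value
  k_family <- length(unique(c(idx[1L, ], idx[2L, ])))
  m <- ncol(idx)
  p_adj <- if (method == "tukey") {
    stats::ptukey(sqrt(2) * abs(t_stat), nmeans = k_family, df = ct$df,
                  lower.tail = FALSE)
  } else {
    pmin(1, m * p_raw)
  }
  # adjusted p can never undercut the raw p (guards rounding at k = 2)
  p_adj <- pmax(p_adj, p_raw)

  data.frame(
    family = family,
    label_a = labels[idx[1L, ]],
    label_b = labels[idx[2L, ]],
    diff = ct$estimate,
    se = ct$SE,
    df = ct$df,
    t = t_stat,
    p_raw = p_raw,
    p_adjusted = p_adj,
    method = method,
    stringsAsFactors = FALSE
  )
}
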