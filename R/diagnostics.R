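#' Marginal residuals of a metabolite fit
#'
#' Residuals about the fixed-effect fit, \eqn{r = y - X\hat\beta}, excluding
#' any predicted random effects — the quantity the residual normality tests
#' and diagnostic plots are based on. One value per retained sample, on the
#' analysis (transformed) scale.
#'
#' @param fit a [fit_metabolite()] result.
#' @return numeric vector of residuals.
#' @export
marginal_residuals <- function(fit) {
  stopifnot(inherits(fit, "metabolite_fit"))
  if (inherits(fit$model, "lmerMod")) {
    y <- lme4::getME(fit$model, "y")
    X <- lme4::getME(fit$model, "X")
    as.numeric(y - X %*% fit$beta)
  } else {
    as.numeric(stats::residuals(fit$model))
  }
}

fitted_marginal <- function(fit) {
  if (inherits(fit$model, "lmerMod")) {
    X <- lme4::getME(fit$model, "X")
    as.numeric(X %*% fit$beta)
  } else {
    as.numeric(stats::fitted(fit$model))
  }
}

#' Shapiro-Wilk normality test of residuals
#'
#' @param residuals numeric vector (3 to 5000 values required).
#' @return list with `statistic` (W) and `p_value`; `NA`s with a warning when
#'   the sample size is out of range.
#' @export
shapiro_wilk <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  n <- length(residuals)
  if (n < 3L || n > 5000L) {
    mn_warn("normality_sample_size",
            sprintf("Shapiro-Wilk needs 3-5000 residuals, got %d", n))
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  t <- stats::shapiro.test(residuals)
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

#' Kolmogorov-Smirnov (Lilliefors) normality test of residuals
#'
#' Lilliefors' version of the Kolmogorov-Smirnov test, appropriate because
#' the residuals' location and scale are estimated from the data. Following
#' the long-standing reporting convention of its tabulated p-values, the
#' reported p-value is capped at 0.15 (`p_reported`); the uncapped value is
#' returned alongside (`p_value`).
#'
#' @param residuals numeric vector (at least 5 values required).
#' @param cap reporting cap for the p-value.
#' @return list with `statistic` (D), `p_value`, `p_reported`.
#' @export
ks_normality <- function(residuals, cap = 0.15) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 5L) {
    mn_warn("normality_sample_size", "Lilliefors test needs at least 5 residuals")
    return(list(statistic = NA_real_, p_value = NA_real_, p_reported = NA_real_))
  }
  t <- nortest::lillie.test(residuals)
  list(statistic = unname(t$statistic),
       p_value = t$p.value,
       p_reported = min(t$p.value, cap))
}

#' Normal quantile-quantile plot data
#'
#' Ordered residuals against theoretical normal quantiles at the Blom
#' plotting positions \eqn{(i - 3/8)/(n + 1/4)}.
#'
#' @param residuals numeric vector.
#' @return data.frame with `theoretical` and `sample` columns, both ordered
#'   nondecreasing in the theoretical axis.
#' @export
qq_data <- function(residuals) {
  r <- sort(residuals[!is.na(residuals)])
  n <- length(r)
  data.frame(
    theoretical = stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4)),
    sample = r
  )
}

#' Diagnostic plot data for one metabolite
#'
#' Computes the data behind the two standard residual diagnostics — the
#' normal quantile-quantile plot and the fitted-values-versus-residuals
#' plot — and optionally writes them as per-metabolite CSV files.
#'
#' @param fit a [fit_metabolite()] result.
#' @param response metabolite name used in file names.
#' @param normgraphpath optional directory for the QQ data CSV.
#' @param fitgraphpath optional directory for the fitted-vs-residual CSV.
#' @return list with data.frames `qq` and `fitted_resid`, invisibly when
#'   files are written.
#' @export
plot_data <- function(fit, response = "metabolite",
                      normgraphpath = NULL, fitgraphpath = NULL) {
  stopifnot(inherits(fit, "metabolite_fit"))
  r <- marginal_residuals(fit)
  out <- list(
    qq = qq_data(r),
    fitted_resid = data.frame(fitted = fitted_marginal(fit), residual = r)
  )
  write_plot <- function(df, dir, suffix) {
    if (is.null(dir)) return()
    if (!dir.exists(dir)) {
      mn_error("unwritable_path", sprintf("plot directory does not exist: %s", dir))
    }
    utils::write.csv(df, file.path(dir, paste0(response, "_", suffix, ".csv")),
                     row.names = FALSE)
  }
  write_plot(out$qq, normgraphpath, "qq")
  write_plot(out$fitted_resid, fitgraphpath, "fitted_resid")
  if (is.null(normgraphpath) && is.null(fitgraphpath)) out else invisible(out)
}
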