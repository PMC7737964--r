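#' Declare the per-metabolite model
#'
#' Captures the design structure every metabolite is analysed under: one or
#' two crossed treatment factors (with interaction in the two-way case), an
#' optional random grouping unit nested inside the treatment cells (pens
#' holding the animals), the normality transformation, the denominator
#' degrees-of-freedom method, and the multiplicity-adjustment choices.
#'
#' @param factor1 name of the first treatment factor (results are sorted by
#'   this factor's p-values downstream).
#' @param factor2 name of the second treatment factor, or `NULL` for one-way
#'   analyses.
#' @param interaction include the factor1:factor2 interaction (two-way only).
#' @param random_unit name of the random grouping column (e.g. `"pen"`),
#'   nested in the treatment cells, or `NULL` for a fixed-effects model.
#' @param transform transformation code, see [normalize_transform_code()].
#' @param ddf_method denominator df method for the fixed-effect tests.
#' @param pairwise_adjust multiplicity adjustment within a pairwise family.
#' @param feature_adjust across-metabolite adjustment of ANOVA p-values.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(factor1, factor2 = NULL, interaction = !is.null(factor2),
                       random_unit = NULL, transform = 1,
                       ddf_method = c("kenward-roger", "satterthwaite"),
                       pairwise_adjust = c("tukey", "bonferroni"),
                       feature_adjust = c("fdr", "bonferroni")) {
  stopifnot(is.character(factor1), length(factor1) == 1L)
  if (!is.null(factor2)) {
    stopifnot(is.character(factor2), length(factor2) == 1L)
    if (identical(factor1, factor2)) {
      mn_error("invalid_spec", "factor1 and factor2 must differ")
    }
  } else if (interaction) {
    mn_error("invalid_spec", "interaction requires a second factor")
  }
  if (!is.null(random_unit) && random_unit %in% c(factor1, factor2)) {
    mn_error("invalid_spec", "the random unit cannot be a treatment factor")
  }
  structure(
    list(
      factor1 = factor1, factor2 = factor2, interaction = interaction,
      random_unit = random_unit,
      transform = normalize_transform_code(transform),
      ddf_method = match.arg(ddf_method),
      pairwise_adjust = match.arg(pairwise_adjust),
      feature_adjust = match.arg(feature_adjust)
    ),
    class = "model_spec"
  )
}

#' Assemble the analysis frame for one metabolite
#'
#' Performs casewise deletion of missing responses, coerces the design
#' columns to factors, builds the nested random-unit factor (units indexed
#' within their treatment cell, so pens sharing a label across cells are
#' still distinct), and checks estimability: at least two observed levels
#' per treatment factor and no empty factorial cell.
#'
#' @param records long-format records for a single metabolite, as produced by
#'   [to_long()]; must contain `value` plus the design columns named in
#'   `spec`.
#' @param spec a [model_spec()].
#' @return a data.frame with the response in `value`, the treatment factors,
#'   and (if any) the nested random unit in `.unit`; attributes `n_used`,
#'   `n_units`, `n_cells` record the design actually fitted.
#' @export
build_model_frame <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  needed <- c("value", spec$factor1, spec$factor2, spec$random_unit)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    mn_error("missing_column",
             sprintf("records lack column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  keep <- !is.na(records$value)
  df <- records[keep, , drop = FALSE]
  if (nrow(df) == 0L) mn_error("degenerate_factor", "no non-missing observations")

  df[[spec$factor1]] <- droplevels(factor(df[[spec$factor1]]))
  if (nlevels(df[[spec$factor1]]) < 2L) {
    mn_error("degenerate_factor",
             sprintf("factor '%s' has a single observed level", spec$factor1))
  }
  if (!is.null(spec$factor2)) {
    df[[spec$factor2]] <- droplevels(factor(df[[spec$factor2]]))
    if (nlevels(df[[spec$factor2]]) < 2L) {
      mn_error("degenerate_factor",
               sprintf("factor '%s' has a single observed level", spec$factor2))
    }
    cells <- table(df[[spec$factor1]], df[[spec$factor2]])
    if (any(cells == 0L)) {
      mn_error("empty_cell",
               "a factorial cell has no observations; interaction not estimable")
    }
    cell <- interaction(df[[spec$factor1]], df[[spec$factor2]], drop = TRUE)
  } else {
    cell <- droplevels(factor(df[[spec$factor1]]))
  }

  n_units <- NA_integer_
  if (!is.null(spec$random_unit)) {
    unit <- interaction(cell, df[[spec$random_unit]], drop = TRUE)
    n_units <- nlevels(unit)
    if (n_units < nlevels(cell)) {
      mn_error("too_few_units",
               "fewer random units than treatment cells; variance not estimable")
    }
    df$.unit <- unit
  }
  out <- df[, needed, drop = FALSE]
  if (!is.null(spec$random_unit)) out$.unit <- df$.unit
  structure(out,
            n_used = nrow(out),
            n_units = n_units,
            n_cells = nlevels(cell))
}

#' Fit the linear mixed model for one metabolite
#'
#' Fits, by REML, the model
#' \deqn{y = \mu + \alpha_k + \gamma_l + (\alpha\gamma)_{kl} + b_{j(kl)} + e,}
#' with sum-to-zero contrasts on all fixed terms (so downstream Wald block
#' tests are the classical Type III tests) and an iid random intercept for
#' the nested unit, \eqn{b \sim N(0, \sigma^2_{unit})}. With no random unit
#' the model reduces to ordinary least squares. The response is expected to
#' be already on the analysis (transformed) scale.
#'
#' @param records long-format records for one metabolite, or a frame from
#'   [build_model_frame()].
#' @param spec a [model_spec()].
#' @return an object of class `metabolite_fit`: a list with the fitted
#'   `model` (`lmerModLmerTest` or `lm`), the analysis `frame`, the `spec`,
#'   `varcomp` (`sigma2_unit`, `sigma2_resid`), fixed-effect `beta` and
#'   covariance `beta_cov`, `reml_loglik`, `n_used`, and flags `converged`
#'   and `singular` (`TRUE` when the unit variance is estimated on the zero
#'   boundary — permitted, but recorded).
#' @export
fit_metabolite <- function(records, spec) {
  frame <- if (is.null(attr(records, "n_used"))) build_model_frame(records, spec) else records
  fixed_terms <- if (!is.null(spec$factor2)) {
    if (spec$interaction) sprintf("%s * %s", spec$factor1, spec$factor2)
    else sprintf("%s + %s", spec$factor1, spec$factor2)
  } else {
    spec$factor1
  }
  contrasts <- stats::setNames(
    as.list(rep("contr.sum", 1L + !is.null(spec$factor2))),
    c(spec$factor1, spec$factor2)
  )

  if (!is.null(spec$random_unit)) {
    fml <- stats::as.formula(paste("value ~", fixed_terms, "+ (1 | .unit)"))
    ctrl <- lme4::lmerControl(
      check.nobs.vs.nlev = "ignore",
      check.nobs.vs.nRE = "ignore",
      calc.derivs = TRUE
    )
    notes <- character()
    model <- withCallingHandlers(
      lmerTest::lmer(fml, data = frame, REML = TRUE,
                     contrasts = contrasts, control = ctrl),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        notes <<- c(notes, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
    opt_ok <- is.null(model@optinfo$conv$opt) || model@optinfo$conv$opt == 0L
    lme4_msgs <- unlist(model@optinfo$conv$lme4$messages)
    converged <- opt_ok && !any(grepl("failed to converge", c(notes, lme4_msgs),
                                      ignore.case = TRUE))
    vc <- as.data.frame(lme4::VarCorr(model))
    sigma2_unit <- vc$vcov[vc$grp == ".unit"]
    sigma2_resid <- vc$vcov[vc$grp == "Residual"]
    fit <- list(
      model = model, frame = frame, spec = spec,
      varcomp = c(sigma2_unit = sigma2_unit, sigma2_resid = sigma2_resid),
      beta = lme4::fixef(model),
      beta_cov = as.matrix(stats::vcov(model)),
      reml_loglik = as.numeric(stats::logLik(model, REML = TRUE)),
      n_used = attr(frame, "n_used"),
      converged = converged,
      singular = lme4::isSingular(model),
      notes = notes
    )
  } else {
    fml <- stats::as.formula(paste("value ~", fixed_terms))
    model <- stats::lm(fml, data = frame, contrasts = contrasts)
    s2 <- summary(model)$sigma^2
    fit <- list(
      model = model, frame = frame, spec = spec,
      varcomp = c(sigma2_unit = 0, sigma2_resid = s2),
      beta = stats::coef(model),
      beta_cov = stats::vcov(model),
      reml_loglik = as.numeric(stats::logLik(model, REML = TRUE)),
      n_used = attr(frame, "n_used"),
      converged = TRUE,
      singular = FALSE,
      notes = character()
    )
  }
  class(fit) <- "metabolite_fit"
  fit
}

#' @export
print.metabolite_fit <- function(x, ...) {
  cat(sprintf(
    "metabolite_fit: n = %d, sigma2_unit = %.4g, sigma2_resid = %.4g%s%s\n",
    x$n_used, x$varcomp[["sigma2_unit"]], x$varcomp[["sigma2_resid"]],
    if (x$singular) " (boundary)" else "",
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}
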