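# Shared fixtures and independent oracles, built in code at test time.

# Balanced 2x2 design: J pens per cell, K animals per pen.
balanced_ft <- function(J = 3, K = 2, s2p = 0.5, s2e = 0.3, n_met = 1,
                        seed = 1, ...) {
  simulate_feature_table(sim_design(
    pens_per_cell = J, animals_per_pen = K,
    sigma2_pen = s2p, sigma2_resid = s2e,
    n_metabolites = n_met, seed = seed, ...
  ))
}

# Long records for one metabolite, response already log-transformed.
met_records <- function(ft, met = 1, transform = 1) {
  long <- to_long(ft)
  rec <- long[long$response_name == ft$metabolite_names[met], , drop = FALSE]
  rec$value <- apply_transform(rec$value, transform)
  rec
}

# Closed-form REML for the balanced nested two-way design: the classical
# nested-ANOVA estimators (within-pen mean square; pen mean square minus
# within, scaled by pen size). Independent of the model-fitting route.
nested_anova_oracle <- function(rec, f1 = "Trx1", f2 = "Trx2", unit = "pen") {
  cell <- interaction(rec[[f1]], rec[[f2]], drop = TRUE)
  pen <- interaction(cell, rec[[unit]], drop = TRUE)
  y <- rec$value
  K <- unique(table(pen))
  stopifnot(length(K) == 1L)  # oracle valid for balanced data only
  pen_mean <- ave(y, pen)
  cell_mean <- ave(y, cell)
  n <- length(y)
  n_pen <- nlevels(pen)
  n_cell <- nlevels(cell)
  ms_within <- sum((y - pen_mean)^2) / (n - n_pen)
  # per-observation sum counts each pen K times: MS_pen = K * pen-level MS
  ms_pen <- sum((pen_mean - cell_mean)^2) / (n_pen - n_cell)
  c(sigma2_unit = max(0, (ms_pen - ms_within) / K), sigma2_resid = ms_within,
    ms_pen = ms_pen, K = K)
}

# Direct REML log-likelihood for the two-variance-component model,
# evaluated from first principles (dense algebra), used as a grid oracle.
reml_loglik_direct <- function(rec, s2p, s2e, f1 = "Trx1", f2 = "Trx2",
                               unit = "pen") {
  cell <- interaction(rec[[f1]], rec[[f2]], drop = TRUE)
  pen <- interaction(cell, rec[[unit]], drop = TRUE)
  y <- rec$value
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X <- model.matrix(~ rec[[f1]] * rec[[f2]])
  Z <- model.matrix(~ pen - 1)
  n <- length(y)
  p <- ncol(X)
  V <- s2p * tcrossprod(Z) + s2e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              t(r) %*% Vi %*% r + (n - p) * log(2 * pi))
  )
}

# Per-metabolite raw ANOVA p-values under the study-shaped design, fitted
# through the package's model path (used for null calibration).
anova_pvalues <- function(ft, spec) {
  long <- to_long(ft)
  t(vapply(ft$metabolite_names, function(met) {
    rec <- long[long$response_name == met, , drop = FALSE]
    rec$value <- apply_transform(rec$value, spec$transform, response = met)
    fit <- fit_metabolite(rec, spec)
    type3_anova(fit)$p_raw
  }, numeric(3)))
}

two_way_spec <- function(...) {
  model_spec("Trx1", "Trx2", random_unit = "pen", ...)
}
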