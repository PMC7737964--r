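test_that("marginal residuals satisfy the GLS normal equations", {
  ft <- balanced_ft(J = 3, K = 2, s2p = 0.4, s2e = 0.3, seed = 61)
  rec <- met_records(ft)
  fit <- fit_metabolite(rec, two_way_spec())
  r <- marginal_residuals(fit)
  expect_length(r, fit$n_used)

  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  X <- model.matrix(~ Trx1 * Trx2, data = fit$frame)
  Z <- model.matrix(~ .unit - 1, data = fit$frame)
  V <- fit$varcomp[["sigma2_unit"]] * tcrossprod(Z) +
    fit$varcomp[["sigma2_resid"]] * diag(nrow(X))
  score <- t(X) %*% solve(V, r)
  expect_true(all(abs(score) < 1e-6))
})

test_that("a saturated fixed-effects fit leaves zero residuals", {
  rec <- data.frame(
    response_name = "m", sample_id = as.character(1:8),
    Trx1 = rep(c("N", "P"), each = 4),
    Trx2 = rep(c("CON", "HFF"), 4),
    stringsAsFactors = FALSE
  )
  rec$value <- c(1, 2, 1, 2, 3, 4, 3, 4)  # exactly the cell-mean pattern
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(
    fit_metabolite(rec, model_spec("Trx1", "Trx2", transform = 0))
  )
  expect_equal(max(abs(marginal_residuals(fit))), 0, tolerance = 1e-10)
})

test_that("Shapiro-Wilk behaves across null, near-perfect and heavy-tailed input", {
  # near-perfect normal input
  sw <- shapiro_wilk(qnorm(((1:50) - 0.5) / 50))
  expect_gt(sw$statistic, 0.99)

  # power against heavy tails at n = 100
  set.seed(71)
  rejections <- vapply(1:500, function(i) {
    shapiro_wilk(rt(100, df = 2))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)

  # size under the null at n = 26 stays inside binomial 99% bounds
  set.seed(73)
  rej_null <- vapply(1:500, function(i) {
    shapiro_wilk(rnorm(26))$p_value < 0.05
  }, logical(1))
  half_width <- 2.576 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej_null) - 0.05), half_width)

  expect_warning(out <- shapiro_wilk(c(1, 2)), class = "normality_sample_size")
  expect_true(is.na(out$p_value))
})

test_that("Lilliefors test caps reported p at 0.15 and detects bimodality", {
  set.seed(79)
  ks <- ks_normality(rnorm(26))
  expect_lte(ks$p_reported, 0.15)
  expect_gte(ks$statistic, 0)
  expect_true(ks$p_value >= ks$p_reported)

  bimodal <- c(rnorm(100, -3), rnorm(100, 3))
  expect_lt(ks_normality(bimodal)$p_value, 0.01)

  expect_warning(out <- ks_normality(c(1, 2, 3)), class = "normality_sample_size")
  expect_true(is.na(out$p_value))
})

test_that("normality p-values are invariant under affine rescaling", {
  set.seed(83)
  r <- rnorm(30)
  r2 <- 5 * r + 3
  expect_equal(shapiro_wilk(r)$p_value, shapiro_wilk(r2)$p_value,
               tolerance = 1e-10)
  expect_equal(ks_normality(r)$p_value, ks_normality(r2)$p_value,
               tolerance = 1e-10)
})

test_that("plot data has the right shape and lands in the requested folders", {
  ft <- simulate_feature_table(feeding_trial_design(n_metabolites = 1, seed = 89))
  fit <- fit_metabolite(met_records(ft), two_way_spec())
  pd <- plot_data(fit)
  expect_equal(nrow(pd$qq), fit$n_used)
  expect_equal(nrow(pd$fitted_resid), fit$n_used)
  expect_true(all(diff(pd$qq$theoretical) > 0))
  expect_true(all(diff(pd$qq$sample) >= 0))

  # simulated normal errors: QQ points track the identity line loosely
  ftn <- balanced_ft(J = 10, K = 2, s2p = 0, s2e = 1, seed = 97)
  fitn <- fit_metabolite(met_records(ftn), model_spec("Trx1", "Trx2", transform = 1))
  qq <- qq_data(marginal_residuals(fitn))
  expect_lt(max(abs(qq$sample - qq$theoretical)), 1)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  plot_data(fit, response = "met001", normgraphpath = d1, fitgraphpath = d2)
  expect_true(file.exists(file.path(d1, "met001_qq.csv")))
  expect_true(file.exists(file.path(d2, "met001_fitted_resid.csv")))
  expect_error(plot_data(fit, normgraphpath = file.path(d1, "nope")),
               class = "unwritable_path")
})
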