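#' Declare a synthetic study design
#'
#' Describes a factorial animal study with the design structure the
#' per-metabolite model assumes: one or two crossed treatment factors,
#' housing pens nested in the treatment cells, and a fixed number of animals
#' per pen (optionally truncated per cell to mimic unbalanced sampling, as
#' when not every animal yields an assayable sample). Metabolite intensities
#' are generated log-normally: on the log scale each metabolite gets fixed
#' treatment effects, a pen random effect with variance `sigma2_pen` and a
#' residual with variance `sigma2_resid`, and the result is exponentiated to
#' a positive peak area. The log transform (`normtrans = 1`) is therefore
#' the correct analysis transform for these data.
#'
#' Cells are ordered with `factor2` varying fastest within `factor1` (for
#' the default labels: N_CON, N_HFF, P_CON, P_HFF); `pens_per_cell` and
#' `samples_per_cell` follow that order. A scalar effect size `e` for a
#' k-level factor places the levels at evenly spaced offsets spanning `e` on
#' the log scale (for 2 levels: -e/2 and +e/2, so `e` is the log-scale
#' difference between levels). The interaction effect (2x2 designs only) is
#' the difference-of-differences on the log scale.
#'
#' @param factor1_levels,factor2_levels level labels; set `factor2_levels`
#'   to `NULL` for a one-way design.
#' @param pens_per_cell pens in each treatment cell (scalar or one value per
#'   cell).
#' @param animals_per_pen animals housed per pen.
#' @param samples_per_cell optional cap on assayed samples per cell
#'   (truncation drops the last animals of a cell's last pens).
#' @param n_metabolites number of response columns to simulate.
#' @param mu_log grand mean of log intensity.
#' @param effect_factor1,effect_factor2,effect_interaction per-metabolite
#'   log-scale effect sizes (scalars are recycled to `n_metabolites`).
#' @param sigma2_pen,sigma2_resid pen and residual variances on the log scale.
#' @param missing_rate probability a measurement is missing, in `[0, 1)`.
#' @param factor1_name,factor2_name,unit_name column names in the generated
#'   table.
#' @param seed integer seed; required, every table is reproducible from it.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(factor1_levels = c("N", "P"),
                       factor2_levels = c("CON", "HFF"),
                       pens_per_cell = 3, animals_per_pen = 2,
                       samples_per_cell = NULL,
                       n_metabolites = 10, mu_log = 10,
                       effect_factor1 = 0, effect_factor2 = 0,
                       effect_interaction = 0,
                       sigma2_pen = 0.05, sigma2_resid = 0.2,
                       missing_rate = 0,
                       factor1_name = "Trx1", factor2_name = "Trx2",
                       unit_name = "pen", seed) {
  if (missing(seed)) mn_error("invalid_design", "a seed is required")
  stopifnot(length(factor1_levels) >= 2L, n_metabolites >= 1L,
            animals_per_pen >= 1L)
  if (sigma2_pen < 0 || sigma2_resid < 0) {
    mn_error("invalid_design", "variances must be nonnegative")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    mn_error("invalid_design", "missing_rate must be in [0, 1)")
  }
  n_cells <- length(factor1_levels) * max(1L, length(factor2_levels))
  pens_per_cell <- rep_len(as.integer(pens_per_cell), n_cells)
  if (any(pens_per_cell < 1L)) mn_error("invalid_design", "need >= 1 pen per cell")
  if (!is.null(samples_per_cell)) {
    samples_per_cell <- rep_len(as.integer(samples_per_cell), n_cells)
    if (any(samples_per_cell > pens_per_cell * animals_per_pen) ||
        any(samples_per_cell < 1L)) {
      mn_error("invalid_design", "samples_per_cell must be in [1, pens x animals]")
    }
  }
  if (!is.null(factor2_levels) && length(factor2_levels) < 2L) {
    mn_error("invalid_design", "factor2 needs >= 2 levels (or NULL for one-way)")
  }
  recycle <- function(x) rep_len(as.numeric(x), n_metabolites)
  structure(
    list(
      factor1_levels = factor1_levels, factor2_levels = factor2_levels,
      pens_per_cell = pens_per_cell, animals_per_pen = as.integer(animals_per_pen),
      samples_per_cell = samples_per_cell, n_metabolites = as.integer(n_metabolites),
      mu_log = mu_log,
      effect_factor1 = recycle(effect_factor1),
      effect_factor2 = recycle(effect_factor2),
      effect_interaction = recycle(effect_interaction),
      sigma2_pen = sigma2_pen, sigma2_resid = sigma2_resid,
      missing_rate = missing_rate,
      factor1_name = factor1_name, factor2_name = factor2_name,
      unit_name = unit_name, seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' A design shaped like a typical two-by-two pig feeding study
#'
#' Two crossed 2-level treatments, pens of paired animals nested in the four
#' treatment cells with 4/3/4/3 pens per cell, and 8/5/8/5 assayed samples
#' per cell (26 in total) — the structure of a liver metabolomics study of
#' diet and probiotic supplementation.
#'
#' @param n_metabolites number of metabolites (default 218).
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_design()].
#' @return a [sim_design()].
#' @export
feeding_trial_design <- function(n_metabolites = 218, seed, ...) {
  sim_design(
    factor1_levels = c("N", "P"), factor2_levels = c("CON", "HFF"),
    pens_per_cell = c(4L, 3L, 4L, 3L), animals_per_pen = 2L,
    samples_per_cell = c(8L, 5L, 8L, 5L),
    n_metabolites = n_metabolites, seed = seed, ...
  )
}

level_offsets <- function(levels, effect) {
  k <- length(levels)
  offs <- if (k == 1L) 0 else effect * (((seq_len(k) - 1) / (k - 1)) - 0.5)
  stats::setNames(offs, levels)
}

#' Simulate a wide-format feature table
#'
#' Draws a [feature_table()] from a [sim_design()]. All randomness is
#' governed by the design's seed: the same design yields an identical table
#' every time. The generating parameters (including the per-metabolite
#' effects) are attached as attribute `"truth"` for recovery tests.
#'
#' @param design a [sim_design()].
#' @return a [feature_table()] whose factors are the unit (pen) column and
#'   the treatment factor(s); metabolites are named `met001`, `met002`, ...
#' @examples
#' ft <- simulate_feature_table(sim_design(n_metabolites = 3, seed = 42))
#' dim(ft)
#' @export
simulate_feature_table <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  d <- design
  one_way <- is.null(d$factor2_levels)
  cells <- if (one_way) {
    data.frame(f1 = d$factor1_levels, stringsAsFactors = FALSE)
  } else {
    expand.grid(f2 = d$factor2_levels, f1 = d$factor1_levels,
                stringsAsFactors = FALSE)[, c("f1", "f2")]
  }
  n_cells <- nrow(cells)

  pen_id <- 0L
  rows <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    pens <- pen_id + seq_len(d$pens_per_cell[ci])
    pen_id <- pen_id + d$pens_per_cell[ci]
    cell_rows <- data.frame(
      pen = rep(sprintf("pen%02d", pens), each = d$animals_per_pen),
      f1 = cells$f1[ci],
      stringsAsFactors = FALSE
    )
    if (!one_way) cell_rows$f2 <- cells$f2[ci]
    if (!is.null(d$samples_per_cell)) {
      cell_rows <- cell_rows[seq_len(d$samples_per_cell[ci]), , drop = FALSE]
    }
    rows[[ci]] <- cell_rows
  }
  frame <- do.call(rbind, rows)
  n <- nrow(frame)
  pens <- unique(frame$pen)

  off1 <- level_offsets(d$factor1_levels, 1)   # unit pattern, scaled per metabolite
  off2 <- if (!one_way) level_offsets(d$factor2_levels, 1)
  inter_sign <- if (!one_way && length(d$factor1_levels) == 2L &&
                    length(d$factor2_levels) == 2L) {
    sign1 <- stats::setNames(c(-1, 1), d$factor1_levels)
    sign2 <- stats::setNames(c(-1, 1), d$factor2_levels)
    sign1[frame$f1] * sign2[frame$f2] / 4
  } else {
    rep(0, n)
  }

  set.seed(d$seed)
  responses <- matrix(NA_real_, nrow = n, ncol = d$n_metabolites,
                      dimnames = list(NULL, sprintf("met%03d", seq_len(d$n_metabolites))))
  for (j in seq_len(d$n_metabolites)) {
    b <- stats::setNames(stats::rnorm(length(pens), 0, sqrt(d$sigma2_pen)), pens)
    e <- stats::rnorm(n, 0, sqrt(d$sigma2_resid))
    log_y <- d$mu_log +
      d$effect_factor1[j] * off1[frame$f1] +
      (if (one_way) 0 else d$effect_factor2[j] * off2[frame$f2]) +
      d$effect_interaction[j] * inter_sign +
      b[frame$pen] + e
    responses[, j] <- exp(log_y)
  }
  if (d$missing_rate > 0) {
    drop <- stats::runif(length(responses)) < d$missing_rate
    responses[drop] <- NA_real_
  }

  factors <- data.frame(pen = frame$pen, stringsAsFactors = FALSE)
  factors[[d$factor1_name]] <- frame$f1
  if (!one_way) factors[[d$factor2_name]] <- frame$f2
  names(factors)[1L] <- d$unit_name

  ft <- feature_table(
    responses = responses,
    factors = factors,
    sample_id = sprintf("S%02d", seq_len(n)),
    treatments = c(d$factor1_name, if (!one_way) d$factor2_name)
  )
  attr(ft, "truth") <- list(
    design = d,
    effects = data.frame(
      metabolite = colnames(responses),
      effect_factor1 = d$effect_factor1,
      effect_factor2 = if (one_way) NA_real_ else d$effect_factor2,
      effect_interaction = d$effect_interaction
    )
  )
  ft
}
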