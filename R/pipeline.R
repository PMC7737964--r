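# Orchestration: per-metabolite analysis, across-metabolite adjustment,
# consolidation into one wide results table mirroring the classic macro
# output (normality block, ANOVA block, LSmeans block, raw and adjusted
# pairwise blocks).

adj_prefix <- c(tukey = "TukeyD", bonferroni = "BonfD")

enumerate_pairs <- function(labels, pairs_filter = NULL) {
  idx <- utils::combn(length(labels), 2L)
  a <- labels[idx[1L, ]]
  b <- labels[idx[2L, ]]
  if (!is.null(pairs_filter)) {
    keep <- paste(a, b, sep = " vs ") %in% pairs_filter |
      paste(b, a, sep = " vs ") %in% pairs_filter
    a <- a[keep]
    b <- b[keep]
  }
  data.frame(label_a = a, label_b = b, stringsAsFactors = FALSE)
}

# Expected levels, cell labels and column schema, fixed across metabolites.
build_schema <- function(ft, spec, cell_adjust, cell_pairs) {
  f1 <- spec$factor1
  f2 <- spec$factor2
  lv1 <- levels(factor(ft$factors[[f1]]))
  lv2 <- if (!is.null(f2)) levels(factor(ft$factors[[f2]]))
  clash <- length(intersect(lv1, lv2)) > 0
  m1 <- if (clash) paste(f1, lv1, sep = "_") else lv1
  m2 <- if (clash) paste(f2, lv2, sep = "_") else lv2
  cells <- if (!is.null(f2)) {
    g <- expand.grid(a = lv1, b = lv2, stringsAsFactors = FALSE)  # f1 fastest
    paste(g$a, g$b, sep = "_")
  }

  lsm_cols <- function(labels) {
    as.vector(rbind(paste0("LS_", labels),
                    paste0("CI_Lower_", labels),
                    paste0("CI_Upper_", labels)))
  }
  pair_cols <- function(prefix, fname, pairs) {
    if (nrow(pairs) == 0L) return(character())
    paste0(prefix, "_", fname, "_", pairs$label_a, "_", pairs$label_b)
  }

  p1 <- enumerate_pairs(lv1)
  p2 <- if (!is.null(f2)) enumerate_pairs(lv2)
  pc <- if (!is.null(f2)) enumerate_pairs(cells, cell_pairs)
  margin_prefix <- adj_prefix[[spec$pairwise_adjust]]
  cells_prefix <- adj_prefix[[cell_adjust]]

  anova_cols <- c(
    paste0(c("Pvalue_", "AdjPvalue_"), f1),
    if (!is.null(f2)) paste0(c("Pvalue_", "AdjPvalue_"), f2),
    if (spec$interaction) c("Pvalue_Inter", "AdjPvalue_Inter")
  )
  lsmeans_cols <- c(lsm_cols(m1),
                    if (!is.null(f2)) c(lsm_cols(m2), lsm_cols(cells)))
  raw_cols <- c(pair_cols("P_valueD", f1, p1),
                if (!is.null(f2)) c(pair_cols("P_valueD", f2, p2),
                                    pair_cols("P_valueD", paste(f1, f2, sep = "_"), pc)))
  adj_cols <- c(pair_cols(margin_prefix, f1, p1),
                if (!is.null(f2)) c(pair_cols(margin_prefix, f2, p2),
                                    pair_cols(cells_prefix, paste(f1, f2, sep = "_"), pc)))

  list(
    f1 = f1, f2 = f2, lv1 = lv1, lv2 = lv2, cells = cells,
    margin1_labels = m1, margin2_labels = m2,
    pairs1 = p1, pairs2 = p2, pairs_cells = pc,
    blocks = list(
      normality = c("Shapiro_Wilk", "Kolmogorov"),
      anova = anova_cols,
      lsmeans = lsmeans_cols,
      pairwise_raw = raw_cols,
      pairwise_adj = adj_cols
    ),
    columns = c("Response", "Transformation",
                "Shapiro_Wilk", "Kolmogorov", anova_cols,
                lsmeans_cols, raw_cols, adj_cols, "Status")
  )
}

# One metabolite: transform -> fit -> tests -> means -> diagnostics.
analyze_metabolite <- function(sub, spec, schema, cell_adjust, cell_pairs,
                               level, normgraphpath, fitgraphpath, lean = FALSE) {
  met <- sub$response_name[1L]
  out <- tryCatch({
    sub$value <- apply_transform(sub$value, spec$transform,
                                 response = met, sample_ids = sub$sample_id)
    fit <- fit_metabolite(sub, spec)
    if (!fit$converged) {
      return(list(status = "no_convergence", response = met))
    }
    anova <- type3_anova(fit)
    if (lean) {
      return(list(status = if (fit$singular) "ok_boundary" else "ok",
                  response = met, anova = anova))
    }
    lsm <- list(factor1 = ls_means(fit, "factor1", level = level))
    pw <- list(factor1 = pairwise_comparisons(fit, "factor1",
                                              method = spec$pairwise_adjust))
    if (!is.null(spec$factor2)) {
      lsm$factor2 <- ls_means(fit, "factor2", level = level)
      lsm$cells <- ls_means(fit, "cells", level = level)
      pw$factor2 <- pairwise_comparisons(fit, "factor2",
                                         method = spec$pairwise_adjust)
      pw$cells <- pairwise_comparisons(fit, "cells", method = cell_adjust,
                                       pairs_filter = cell_pairs)
    }
    r <- marginal_residuals(fit)
    sw <- withCallingHandlers(
      shapiro_wilk(r),
      metanova_warning = function(w) invokeRestart("muffleWarning")
    )
    ks <- withCallingHandlers(
      ks_normality(r),
      metanova_warning = function(w) invokeRestart("muffleWarning")
    )
    if (!is.null(normgraphpath) || !is.null(fitgraphpath)) {
      plot_data(fit, response = met,
                normgraphpath = normgraphpath, fitgraphpath = fitgraphpath)
    }
    list(
      status = if (fit$singular) "ok_boundary" else "ok",
      response = met, fit = fit, anova = anova, lsmeans = lsm, pairwise = pw,
      shapiro = sw, ks = ks
    )
  },
  metanova_error = function(e) list(status = class(e)[1L], response = met),
  error = function(e) list(status = paste0("error: ", conditionMessage(e)),
                           response = met))
  out
}

consolidate_row <- function(res, spec, schema) {
  cols <- schema$columns
  row <- stats::setNames(as.list(rep(NA_real_, length(cols))), cols)
  row$Response <- res$response
  row$Transformation <- transform_label(spec$transform)
  row$Status <- res$status

  if (!is.null(res$anova)) {
    a <- res$anova
    row[[paste0("Pvalue_", schema$f1)]] <- a$p_raw[a$effect == schema$f1]
    if (!is.null(schema$f2)) {
      row[[paste0("Pvalue_", schema$f2)]] <- a$p_raw[a$effect == schema$f2]
      if (spec$interaction) {
        row[["Pvalue_Inter"]] <-
          a$p_raw[a$effect == paste(schema$f1, schema$f2, sep = ":")]
      }
    }
  }
  if (!is.null(res$shapiro)) {
    row$Shapiro_Wilk <- res$shapiro$p_value
    row$Kolmogorov <- res$ks$p_reported
  }
  if (!is.null(res$lsmeans)) {
    set_lsm <- function(df, labels, schema_labels) {
      for (i in seq_along(labels)) {
        j <- match(labels[i], df$label)
        if (is.na(j)) next
        row[[paste0("LS_", schema_labels[i])]] <<- df$bt_estimate[j]
        row[[paste0("CI_Lower_", schema_labels[i])]] <<- df$bt_lower[j]
        row[[paste0("CI_Upper_", schema_labels[i])]] <<- df$bt_upper[j]
      }
    }
    set_lsm(res$lsmeans$factor1, schema$lv1, schema$margin1_labels)
    if (!is.null(schema$f2)) {
      set_lsm(res$lsmeans$factor2, schema$lv2, schema$margin2_labels)
      set_lsm(res$lsmeans$cells, schema$cells, schema$cells)
    }
  }
  if (!is.null(res$pairwise)) {
    set_pairs <- function(df, fname, pairs, raw_prefix, adjp) {
      for (i in seq_len(nrow(pairs))) {
        j <- which((df$label_a == pairs$label_a[i] & df$label_b == pairs$label_b[i]) |
                   (df$label_a == pairs$label_b[i] & df$label_b == pairs$label_a[i]))
        if (!length(j)) next
        suffix <- paste0(fname, "_", pairs$label_a[i], "_", pairs$label_b[i])
        row[[paste0(raw_prefix, "_", suffix)]] <<- df$p_raw[j]
        row[[paste0(adjp, "_", suffix)]] <<- df$p_adjusted[j]
      }
    }
    mp <- adj_prefix[[spec$pairwise_adjust]]
    set_pairs(res$pairwise$factor1, schema$f1, schema$pairs1, "P_valueD", mp)
    if (!is.null(schema$f2)) {
      cp <- adj_prefix[[res$pairwise$cells$method[1L]]]
      set_pairs(res$pairwise$factor2, schema$f2, schema$pairs2, "P_valueD", mp)
      set_pairs(res$pairwise$cells, paste(schema$f1, schema$f2, sep = "_"),
                schema$pairs_cells, "P_valueD", cp)
    }
  }
  row
}

run_pipeline <- function(ft, spec, cell_adjust, cell_pairs, level,
                         respath, name, singlefile, normgraphpath, fitgraphpath,
                         round_digits, verbose) {
  schema <- build_schema(ft, spec, cell_adjust, cell_pairs)
  long <- to_long(ft)
  split_long <- split(long, factor(long$response_name, levels = ft$metabolite_names))

  rows <- vector("list", length(ft$metabolite_names))
  for (i in seq_along(ft$metabolite_names)) {
    res <- analyze_metabolite(split_long[[i]], spec, schema, cell_adjust,
                              cell_pairs, level, normgraphpath, fitgraphpath)
    rows[[i]] <- consolidate_row(res, spec, schema)
    if (verbose) {
      message(sprintf("[%d/%d] %s: %s", i, length(rows),
                      ft$metabolite_names[i], rows[[i]]$Status))
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))

  # across-metabolite adjustment, one family per effect
  effects <- c(schema$f1, schema$f2, if (spec$interaction) "Inter")
  raw_cols <- paste0("Pvalue_", effects)
  adj_cols <- paste0("AdjPvalue_", effects)
  tests <- do.call(rbind, lapply(seq_along(effects), function(k) {
    data.frame(response = tab$Response, effect = effects[k],
               p_raw = tab[[raw_cols[k]]], stringsAsFactors = FALSE)
  }))
  tests <- adjust_all_effects(tests, method = spec$feature_adjust)
  for (k in seq_along(effects)) {
    tab[[adj_cols[k]]] <- tests$p_adjusted[tests$effect == effects[k]]
  }

  p1 <- tab[[paste0("Pvalue_", schema$f1)]]
  tab <- tab[order(is.na(p1), p1), , drop = FALSE]
  rownames(tab) <- NULL

  result <- structure(
    list(table = tab, blocks = schema$blocks, spec = spec, schema = schema,
         n_samples = nrow(ft$responses), n_metabolites = length(ft$metabolite_names)),
    class = "metanova_result"
  )
  if (!is.null(respath)) {
    export_results(result, respath, name = name, singlefile = singlefile,
                   round_digits = round_digits)
  }
  result
}

resolve_input <- function(input, factor1, factor2, exclude_vars, ignore_vars,
                          strict_names) {
  if (inherits(input, "feature_table")) return(input)
  read_wide_table(input, treatment_var1 = factor1, treatment_var2 = factor2,
                  exclude_vars = exclude_vars, ignore_vars = ignore_vars,
                  strict_names = strict_names)
}

#' Run the two-way per-metabolite mixed-model analysis
#'
#' For every metabolite: transform the response, fit the linear mixed model
#' with both treatments, their interaction and the nested random unit by
#' REML, run the Kenward-Roger adjusted Type III ANOVA, compute
#' back-transformed LSmeans with confidence intervals for both margins and
#' the cells, compute raw and multiplicity-adjusted pairwise comparisons,
#' and test residual normality. ANOVA p-values are then adjusted across
#' metabolites (FDR or Bonferroni) per effect, and everything is
#' consolidated into one wide table sorted by the first factor's raw ANOVA
#' p-value. A metabolite whose fit fails is kept as a row of `NA`s with the
#' failure reason in `Status`; it never aborts the run.
#'
#' @param input path to a wide-format CSV (see [read_wide_table()]) or a
#'   [feature_table()].
#' @param factor1,factor2 treatment factor column names; results are sorted
#'   by `factor1`'s p-values.
#' @param random_unit random grouping column nested in the treatment cells
#'   (e.g. `"pen"`), or `NULL` for a fixed-effects analysis.
#' @param exclude_vars,ignore_vars passed to [read_wide_table()] when `input`
#'   is a path.
#' @param normtrans transformation code: 0 none, 1 log (default), 2 sqrt.
#' @param pval_adjust across-metabolite adjustment: `"fdr"` or `"bonferroni"`.
#' @param pairwise_adjust within-family adjustment for marginal comparisons:
#'   `"tukey"` or `"bonferroni"`.
#' @param cell_adjust adjustment for cell-mean (simple-effect) comparisons;
#'   defaults to `pairwise_adjust`. Bonferroni with a restricted
#'   `cell_pairs` family is recommended when the interaction is of interest.
#' @param cell_pairs optional character vector restricting the cell
#'   comparisons, entries `"<lvl1>_<lvl2> vs <lvl1>_<lvl2>"`.
#' @param level confidence level for LSmean intervals.
#' @param respath optional existing directory: results are exported there.
#' @param name base name for exported files.
#' @param singlefile one consolidated CSV (`TRUE`) or one CSV per component.
#' @param normgraphpath,fitgraphpath optional directories for per-metabolite
#'   QQ and fitted-vs-residual plot data.
#' @param strict_names escalate metabolite-name violations to errors.
#' @param round_digits optional significant digits for exported files.
#' @param verbose print per-metabolite progress.
#' @return a `metanova_result`: list with the consolidated `table`, the
#'   column `blocks`, and the model `spec`.
#' @examples
#' ft <- simulate_feature_table(sim_design(n_metabolites = 2, seed = 7))
#' res <- run_two_way(ft, "Trx1", "Trx2", random_unit = "pen")
#' res$table[, 1:6]
#' @export
run_two_way <- function(input, factor1, factor2, random_unit = NULL,
                        exclude_vars = character(), ignore_vars = character(),
                        normtrans = 1, pval_adjust = c("fdr", "bonferroni"),
                        pairwise_adjust = c("tukey", "bonferroni"),
                        cell_adjust = NULL, cell_pairs = NULL, level = 0.95,
                        respath = NULL, name = "metanova_results",
                        singlefile = TRUE,
                        normgraphpath = NULL, fitgraphpath = NULL,
                        strict_names = FALSE, round_digits = NULL,
                        verbose = FALSE) {
  pval_adjust <- match.arg(pval_adjust)
  pairwise_adjust <- match.arg(pairwise_adjust)
  if (is.null(cell_adjust)) cell_adjust <- pairwise_adjust
  cell_adjust <- match.arg(cell_adjust, c("tukey", "bonferroni"))
  ft <- resolve_input(input, factor1, factor2, exclude_vars, ignore_vars,
                      strict_names)
  spec <- model_spec(factor1, factor2, interaction = TRUE,
                     random_unit = random_unit, transform = normtrans,
                     pairwise_adjust = pairwise_adjust,
                     feature_adjust = pval_adjust)
  run_pipeline(ft, spec, cell_adjust, cell_pairs, level, respath, name,
               singlefile, normgraphpath, fitgraphpath, round_digits, verbose)
}

#' Run the one-way per-metabolite analysis
#'
#' Same per-metabolite workflow as [run_two_way()] with a single treatment
#' factor: one ANOVA effect per metabolite, LSmeans per level, and all
#' pairwise level comparisons (Tukey-Kramer by default).
#'
#' @inheritParams run_two_way
#' @param factor the treatment factor column name.
#' @param random_unit random grouping column nested in the treatment levels,
#'   or `NULL`.
#' @return a `metanova_result`.
#' @export
run_one_way <- function(input, factor, random_unit = NULL,
                        exclude_vars = character(), ignore_vars = character(),
                        normtrans = 1, pval_adjust = c("fdr", "bonferroni"),
                        pairwise_adjust = c("tukey", "bonferroni"),
                        level = 0.95, respath = NULL,
                        name = "metanova_results", singlefile = TRUE,
                        normgraphpath = NULL, fitgraphpath = NULL,
                        strict_names = FALSE, round_digits = NULL,
                        verbose = FALSE) {
  pval_adjust <- match.arg(pval_adjust)
  pairwise_adjust <- match.arg(pairwise_adjust)
  ft <- resolve_input(input, factor, NULL, exclude_vars, ignore_vars,
                      strict_names)
  spec <- model_spec(factor, NULL, interaction = FALSE,
                     random_unit = random_unit, transform = normtrans,
                     pairwise_adjust = pairwise_adjust,
                     feature_adjust = pval_adjust)
  run_pipeline(ft, spec, pairwise_adjust, NULL, level, respath, name,
               singlefile, normgraphpath, fitgraphpath, round_digits, verbose)
}

#' @export
print.metanova_result <- function(x, ...) {
  ok <- grepl("^ok", x$table$Status)
  cat(sprintf(
    "metanova_result: %d metabolites x %d samples; %d fits ok (%d boundary), %d failed\n",
    x$n_metabolites, x$n_samples, sum(ok),
    sum(x$table$Status == "ok_boundary"), sum(!ok)
  ))
  cat(sprintf("  transformation: %s; across-metabolite adjustment: %s\n",
              transform_label(x$spec$transform), x$spec$feature_adjust))
  p1 <- paste0("Pvalue_", x$spec$factor1)
  top <- utils::head(x$table[, c("Response", p1, paste0("Adj", p1), "Status")], 5L)
  print(top, row.names = FALSE)
  invisible(x)
}
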