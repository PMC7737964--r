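#' Wide-format feature table
#'
#' A `feature_table` holds one study's metabolite measurements in the layout
#' the pipeline expects: one row per sample, design factors kept apart from
#' the response (metabolite) columns, and missing peak areas recorded as `NA`.
#'
#' @param responses numeric matrix, samples x metabolites; column names are
#'   the metabolite names.
#' @param factors data.frame of design columns (treatments and any excluded
#'   variables such as animal or pen identifiers), one row per sample.
#' @param sample_id character vector of sample identifiers.
#' @param treatments character vector naming the treatment factor column(s)
#'   inside `factors` (length 1 or 2); may be `NULL` when unknown.
#' @return an object of class `feature_table` with elements `sample_id`,
#'   `factors`, `responses`, `metabolite_names`, `treatments`.
#' @export
feature_table <- function(responses, factors, sample_id = NULL, treatments = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  if (ncol(responses) < 1L) {
    mn_error("no_response_columns", "a feature table needs at least one response column")
  }
  if (is.null(colnames(responses)) || anyDuplicated(colnames(responses))) {
    mn_error("invalid_metabolite_names", "metabolite names must be present and unique")
  }
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != nrow(responses)) {
    mn_error("dimension_mismatch", "factors and responses must have the same rows")
  }
  overlap <- intersect(names(factors), colnames(responses))
  if (length(overlap)) {
    mn_error("column_overlap",
             sprintf("columns are both factor and response: %s",
                     paste(overlap, collapse = ", ")))
  }
  if (is.null(sample_id)) sample_id <- as.character(seq_len(nrow(responses)))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(responses)) {
    mn_error("dimension_mismatch", "sample_id length must match the number of rows")
  }
  if (!is.null(treatments) && !all(treatments %in% names(factors))) {
    mn_error("missing_column", "treatment columns must be present among the factors")
  }
  structure(
    list(
      sample_id = sample_id,
      factors = factors,
      responses = responses,
      metabolite_names = colnames(responses),
      treatments = treatments
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples x %d metabolites; factors: %s\n",
    nrow(x$responses), ncol(x$responses),
    paste(names(x$factors), collapse = ", ")
  ))
  n_na <- sum(is.na(x$responses))
  if (n_na > 0) cat(sprintf("  missing response cells: %d\n", n_na))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$responses)

#' Read a wide-format metabolomics CSV
#'
#' Reads a comma-delimited table with a header row in which every column is
#' either a design variable or one metabolite's peak areas. Missing
#' measurements are encoded as a dot (`.`); empty cells are also accepted.
#' Columns listed in `exclude_vars` are kept as design factors but never
#' treated as responses (e.g. animal and pen identifiers); columns listed in
#' `ignore_vars` are dropped entirely. Every remaining column that is not a
#' treatment is taken to be a metabolite.
#'
#' @param path path to the CSV file.
#' @param treatment_var1 name of the first treatment column. The consolidated
#'   results are later sorted by this factor's ANOVA p-value, so put the
#'   factor of primary interest first.
#' @param treatment_var2 name of the second treatment column, or `NULL` for
#'   one-way designs.
#' @param exclude_vars columns used in the model (or kept for bookkeeping)
#'   but not analysed as responses.
#' @param ignore_vars columns dropped entirely.
#' @param strict_names if `TRUE`, metabolite-name violations (see
#'   [validate_names()]) raise an error instead of a warning.
#' @param missing_tokens tokens parsed as missing; `.` is canonical.
#' @return a [feature_table()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("pig,pen,Trx1,Trx2,met1,met2",
#'              "1,p1,N,CON,1.5,2.0",
#'              "2,p1,N,CON,.,2.5"), tf)
#' ft <- read_wide_table(tf, "Trx1", "Trx2", exclude_vars = c("pig", "pen"))
#' dim(ft)
#' @export
read_wide_table <- function(path, treatment_var1, treatment_var2 = NULL,
                            exclude_vars = character(), ignore_vars = character(),
                            strict_names = FALSE, missing_tokens = c(".", "")) {
  if (!file.exists(path)) {
    mn_error("file_not_found", sprintf("input file not found: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  treatments <- c(treatment_var1, treatment_var2)
  declared <- unique(c(treatments, exclude_vars, ignore_vars))
  missing_cols <- setdiff(declared, names(raw))
  if (length(missing_cols)) {
    mn_error("missing_column",
             sprintf("declared column(s) not in header: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, setdiff(names(raw), ignore_vars), drop = FALSE]
  factor_cols <- unique(c(treatments, setdiff(exclude_vars, ignore_vars)))
  response_cols <- setdiff(names(raw), factor_cols)
  if (length(response_cols) == 0L) {
    mn_error("no_response_columns", "no metabolite columns remain after exclusions")
  }

  report <- validate_names(response_cols)
  if (!report$is_clean) {
    msg <- sprintf(
      "%d metabolite name(s) violate naming rules (e.g. %s)",
      nrow(report$violations),
      paste(utils::head(unique(report$violations$name), 3L), collapse = ", ")
    )
    if (strict_names) mn_error("invalid_metabolite_names", msg) else
      mn_warn("invalid_metabolite_names", msg)
  }

  parse_col <- function(col) {
    x <- trimws(raw[[col]])
    x[x %in% missing_tokens] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      mn_error("invalid_numeric",
               sprintf("non-numeric value '%s' in response column '%s', row %d",
                       x[bad[1L]], col, bad[1L]))
    }
    out
  }
  responses <- vapply(response_cols, parse_col, numeric(nrow(raw)))
  responses <- matrix(responses, nrow = nrow(raw),
                      dimnames = list(NULL, response_cols))

  feature_table(
    responses = responses,
    factors = raw[, factor_cols, drop = FALSE],
    treatments = treatments
  )
}

#' Check variable names against portable naming rules
#'
#' Flags names that are 32 characters or longer, contain characters other
#' than letters, digits and underscores, or start with a digit. Such names
#' break round-tripping with the SAS-based workflows common in metabolomics
#' cores, so the reader warns about them by default.
#'
#' @param names character vector of candidate column names.
#' @return a list with `violations` (data.frame of `name`, `rule`) and
#'   `is_clean` (`TRUE` iff no violations).
#' @examples
#' validate_names(c("pyridoxate", "C18:1 FA"))
#' @export
validate_names <- function(names) {
  names <- as.character(names)
  rules <- list(
    too_long = nchar(names) >= 32L,
    special_characters = grepl("[^A-Za-z0-9_]", names),
    leading_digit = grepl("^[0-9]", names)
  )
  violations <- do.call(rbind, lapply(names(rules), function(rule) {
    hit <- rules[[rule]]
    if (!any(hit)) return(NULL)
    data.frame(name = names[hit], rule = rule, stringsAsFactors = FALSE)
  }))
  if (is.null(violations)) {
    violations <- data.frame(name = character(), rule = character(),
                             stringsAsFactors = FALSE)
  }
  list(violations = violations, is_clean = nrow(violations) == 0L)
}

#' Reshape a feature table to long format
#'
#' Produces one record per (sample, metabolite) pair, grouped by metabolite
#' and preserving the original sample order within each group — the layout
#' under which the per-metabolite models are fitted.
#'
#' @param table a [feature_table()].
#' @return a data.frame with columns `response_name`, `value`, `sample_id`
#'   and one column per design factor.
#' @export
to_long <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$responses)
  m <- ncol(table$responses)
  out <- data.frame(
    response_name = rep(table$metabolite_names, each = n),
    value = as.vector(table$responses),
    sample_id = rep(table$sample_id, times = m),
    stringsAsFactors = FALSE
  )
  cbind(out, table$factors[rep(seq_len(n), times = m), , drop = FALSE],
        row.names = NULL)
}

#' Write a feature table as a wide CSV
#'
#' Inverse of [read_wide_table()]: design factors first, then one column per
#' metabolite, with missing measurements written as the canonical dot (`.`).
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @param missing_token token written for missing values.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(table, path, missing_token = ".") {
  stopifnot(inherits(table, "feature_table"))
  resp <- as.data.frame(table$responses)
  resp[] <- lapply(resp, function(x) {
    out <- as.character(x)
    out[is.na(x)] <- missing_token
    out
  })
  out <- cbind(table$factors, resp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export consolidated results to CSV
#'
#' Writes either one consolidated file with the full column schema, or one
#' file per result component (normality tests, ANOVA p-values, LSmeans,
#' raw pairwise p-values, adjusted pairwise p-values). Rows are written in
#' the result's order: ascending in the first treatment factor's raw ANOVA
#' p-value, metabolites with failed fits last.
#'
#' @param result a `metanova_result` from [run_two_way()] or [run_one_way()].
#' @param respath existing directory to write into.
#' @param name base file name (without extension); spaces are replaced by
#'   underscores.
#' @param singlefile if `TRUE` (default) write one consolidated CSV,
#'   otherwise one CSV per component.
#' @param round_digits optional number of significant digits for the output
#'   (full precision by default).
#' @return character vector of the files written, invisibly.
#' @export
export_results <- function(result, respath, name = "metanova_results",
                           singlefile = TRUE, round_digits = NULL) {
  stopifnot(inherits(result, "metanova_result"))
  if (!dir.exists(respath)) {
    mn_error("unwritable_path", sprintf("results directory does not exist: %s", respath))
  }
  if (grepl(" ", name)) {
    mn_warn("path_with_spaces", "spaces in output name replaced by underscores")
    name <- gsub(" ", "_", name)
  }
  tab <- result$table
  if (nrow(tab) == 0L) mn_error("empty_results", "no rows to export")
  if (!is.null(round_digits)) {
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = round_digits)
  }
  write_one <- function(df, file) {
    ok <- tryCatch({
      utils::write.csv(df, file, row.names = FALSE, na = ".")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) mn_error("unwritable_path", sprintf("cannot write %s", file))
    file
  }
  if (singlefile) {
    files <- write_one(tab, file.path(respath, paste0(name, ".csv")))
  } else {
    lead <- c("Response", "Transformation")
    files <- vapply(names(result$blocks), function(component) {
      cols <- c(lead, result$blocks[[component]], "Status")
      cols <- intersect(cols, names(tab))
      write_one(tab[, cols, drop = FALSE],
                file.path(respath, paste0(name, "_", component, ".csv")))
    }, character(1))
  }
  invisible(unname(files))
}
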