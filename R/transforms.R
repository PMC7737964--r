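#' Normality transformations
#'
#' Metabolite peak areas are typically right-skewed; the analysis pipeline
#' therefore supports transforming every response before model fitting and
#' back-transforming estimates for reporting. Three transformations are
#' available, identified by an integer code mirroring the pipeline's
#' `normtrans` option: `0` (none), `1` (natural log, the default), and
#' `2` (square root).
#'
#' @param code transformation code: `0`/`"none"`, `1`/`"log"`, `2`/`"sqrt"`.
#' @return `normalize_transform_code()` returns the integer code;
#'   `transform_label()` returns `"none"`, `"log"` or `"sqrt"`.
#' @keywords internal
#' @export
normalize_transform_code <- function(code) {
  labels <- c(none = 0L, log = 1L, sqrt = 2L)
  if (is.character(code)) {
    code <- match.arg(tolower(code), names(labels))
    return(labels[[code]])
  }
  if (length(code) != 1L || is.na(code) || !code %in% labels) {
    mn_error("invalid_transform_code",
             "transformation code must be 0 (none), 1 (log) or 2 (sqrt)")
  }
  as.integer(code)
}

#' @rdname normalize_transform_code
#' @export
transform_label <- function(code) {
  c("none", "log", "sqrt")[normalize_transform_code(code) + 1L]
}

#' Apply a normality transformation to a response vector
#'
#' Missing values are preserved. The log transform is the natural log and
#' requires strictly positive values; the square root requires nonnegative
#' values. Domain violations name the response and the offending samples so
#' that a per-metabolite failure can be reported without stopping a run.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param code transformation code (see [normalize_transform_code()]).
#' @param response optional response name used in error messages.
#' @param sample_ids optional sample identifiers used in error messages.
#' @return transformed numeric vector of the same length.
#' @examples
#' apply_transform(c(1, exp(1), NA), 1)
#' apply_transform(c(0, 4, 9), 2)
#' @export
apply_transform <- function(values, code, response = NULL, sample_ids = NULL) {
  code <- normalize_transform_code(code)
  if (code == 0L) return(values)
  bad <- if (code == 1L) !is.na(values) & values <= 0 else !is.na(values) & values < 0
  if (any(bad)) {
    ids <- if (is.null(sample_ids)) which(bad) else sample_ids[bad]
    mn_error(
      "transform_domain",
      sprintf(
        "%s transform undefined for response '%s' at sample(s) %s",
        transform_label(code),
        if (is.null(response)) "<unnamed>" else response,
        paste(ids, collapse = ", ")
      )
    )
  }
  if (code == 1L) log(values) else sqrt(values)
}

#' Back-transform estimates to the original measurement scale
#'
#' `back_transform()` inverts [apply_transform()] elementwise;
#' `back_transform_interval()` maps a point estimate together with its
#' confidence limits. Both maps are monotone on their domains, so interval
#' ordering is preserved.
#'
#' @param x,estimate,lower,upper values on the transformed (analysis) scale.
#' @param code transformation code (see [normalize_transform_code()]).
#' @return `back_transform()` a numeric vector; `back_transform_interval()`
#'   a named list with elements `estimate`, `lower`, `upper`.
#' @examples
#' back_transform_interval(0, -1, 1, code = 1)
#' @export
back_transform <- function(x, code) {
  code <- normalize_transform_code(code)
  switch(as.character(code), "0" = x, "1" = exp(x), "2" = x^2)
}

#' @rdname back_transform
#' @export
back_transform_interval <- function(estimate, lower, upper, code) {
  code <- normalize_transform_code(code)
  ok <- is.na(lower) | is.na(estimate) | is.na(upper) |
    (lower <= estimate & estimate <= upper)
  if (!all(ok)) {
    mn_error("invalid_interval", "interval must satisfy lower <= estimate <= upper")
  }
  if (code == 2L) {
    neg <- c(estimate, lower, upper)
    if (any(!is.na(neg) & neg < 0)) {
      mn_error("invalid_interval",
               "sqrt-scale interval must be nonnegative before squaring")
    }
  }
  list(
    estimate = back_transform(estimate, code),
    lower = back_transform(lower, code),
    upper = back_transform(upper, code)
  )
}
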