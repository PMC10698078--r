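#' @importFrom rlang abort warn .data :=
#' @importFrom stats setNames
NULL

# classed conditions so callers can branch on failure mode
stop_mycotrace <- function(class, message, ...) {
  abort(message, class = c(paste0("mycotrace_error_", class), "mycotrace_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, class = "invalid_argument",
                         allow_na = FALSE) {
  if (!is.numeric(x)) {
    stop_mycotrace(class, sprintf("`%s` must be numeric.", name))
  }
  bad <- !is.finite(x)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop_mycotrace(class, sprintf("`%s` contains non-finite values.", name))
  }
  out_of_range <- x < lower | x > upper
  if (any(out_of_range, na.rm = TRUE)) {
    stop_mycotrace(class, sprintf(
      "`%s` must lie in [%s, %s]; offending values: %s.",
      name, format(lower), format(upper),
      paste(utils::head(format(x[which(out_of_range)]), 5), collapse = ", ")
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_mycotrace("missing_column", sprintf(
      "%s is missing required column(s): %s.", table_name,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# standard error of the mean, NA-safe
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
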