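#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a linear fit
#'
#' One row per coefficient, in the broom column convention.
#'
#' @param x A `linear_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  t_int <- x$intercept / x$se_intercept
  t_slp <- x$slope / x$se_slope
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    statistic = c(t_int, t_slp),
    p.value = c(2 * stats::pt(abs(t_int), x$residual_df, lower.tail = FALSE),
                x$p_slope)
  )
}

#' @rdname tidy.linear_fit
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, r.squared = x$r^2, p.value = x$p_slope,
    nobs = x$n, df.residual = x$residual_df
  )
}

#' @method tidy slope_test
#' @export
tidy.slope_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$slope, reference = x$reference_value,
    std.error = x$se, statistic = x$t_statistic,
    df = x$df, p.value = x$p_value, alternative = x$direction
  )
}

#' @method tidy threshold_estimate
#' @export
tidy.threshold_estimate <- function(x, ...) {
  tibble::tibble(
    x_intercept = x$x_intercept, ci_low = x$ci_low, ci_high = x$ci_high,
    conf.level = x$level, n_bootstrap = x$n_bootstrap, seed = x$seed
  )
}

#' @method tidy anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble::tibble(
    r_statistic = x$r_statistic, p.value = x$p_value,
    n_permutations = x$n_permutations, seed = x$seed, nobs = x$n
  )
}

#' @method tidy anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) {
  x$pairwise |>
    dplyr::transmute(
      contrast = paste(.data$group1, "-", .data$group2),
      estimate = .data$diff, std.error = .data$se,
      statistic = .data$q, adj.p.value = .data$p_adj
    )
}

#' @method glance anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_statistic, p.value = x$p_value,
    df = x$df[["term"]], df.residual = x$df[["residual"]],
    log_transformed = x$log_transformed
  )
}
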