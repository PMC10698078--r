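# exact (noise-free) inputs are a supported case: silence lm's advisory
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

new_linear_fit <- function(fit, x, y) {
  cf <- quiet_summary(fit)$coefficients
  structure(
    list(
      slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
      se_slope = unname(cf[2, 2]), se_intercept = unname(cf[1, 2]),
      r = stats::cor(x, y), p_slope = unname(cf[2, 4]),
      n = length(x), residual_df = length(x) - 2L,
      x = x, y = y
    ),
    class = "linear_fit"
  )
}

check_xy <- function(x, y, min_n = 3) {
  if (length(x) != length(y)) {
    stop_mycotrace("invalid_argument", "x and y must have equal length.")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n) {
    stop_mycotrace("degenerate_design",
                   sprintf("Need at least %d complete (x, y) pairs.", min_n))
  }
  if (stats::var(x) == 0) {
    stop_mycotrace("degenerate_design",
                   "x is constant; slope is not identifiable.")
  }
  list(x = x, y = y)
}

#' Ordinary least-squares line for an enrichment relationship
#'
#' Fits `y = intercept + slope * x` by OLS and returns the quantities the
#' enrichment-stoichiometry analyses need: slope and intercept with standard
#' errors, Pearson's r, the two-sided p-value of the slope (t on n-2 df), and
#' the sample size. The fitted data are kept on the object so bootstrap
#' methods ([x_intercept_threshold()]) and [autoplot.linear_fit()] can reuse
#' them.
#'
#' @param x,y Numeric vectors (pairs with missing values are dropped);
#'   at least 3 complete pairs and non-constant x.
#' @return A `linear_fit` object; see also [tidy.linear_fit()] and
#'   [glance.linear_fit()].
#' @examples
#' fit_linear(1:10, 2 * (1:10) + rnorm(10))
#' @export
fit_linear <- function(x, y) {
  xy <- check_xy(x, y)
  if (stats::var(xy$y) == 0) {
    # flat response: lm still works, r defined as 0 by convention
    fit <- stats::lm(y ~ x, data = xy)
    out <- new_linear_fit(fit, xy$x, xy$y)
    out$r <- 0
    return(out)
  }
  fit <- stats::lm(y ~ x, data = xy)
  new_linear_fit(fit, xy$x, xy$y)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.4g x + %.4g\n", x$n, x$slope, x$intercept))
  cat(sprintf("  slope SE %.4g, R = %.3f, P(slope) = %.4g\n",
              x$se_slope, x$r, x$p_slope))
  invisible(x)
}

#' Test a regression slope against a reference value
#'
#' `t = (slope - reference) / SE(slope)` on n-2 residual df. Used to ask
#' whether the coupling of ectomycorrhizal to lateral-root enrichment departs
#' from proportionality (reference 1: the symbiont is neither enriched nor
#' diluted relative to its supporting rootlet).
#'
#' @inheritParams fit_linear
#' @param reference_value Null slope (default 1).
#' @param direction `"two.sided"`, `"greater"` or `"less"`.
#' @return A `slope_test` object: slope, reference, t, df, p, direction.
#' @export
test_slope_against_value <- function(x, y, reference_value = 1,
                                     direction = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  fit <- fit_linear(x, y)
  diff <- fit$slope - reference_value
  # (numerically) exact fits have zero residual SE; the test is then
  # degenerate but its limit is well defined: no evidence against an equal
  # slope, certain evidence against a different one
  scale_ref <- max(abs(fit$slope), abs(reference_value), 1)
  if (fit$se_slope <= 1e-10 * scale_ref) {
    t_stat <- if (abs(diff) <= 1e-8 * scale_ref) 0 else sign(diff) * Inf
  } else {
    t_stat <- diff / fit$se_slope
  }
  p <- switch(direction,
    two.sided = 2 * stats::pt(abs(t_stat), fit$residual_df, lower.tail = FALSE),
    greater = stats::pt(t_stat, fit$residual_df, lower.tail = FALSE),
    less = stats::pt(t_stat, fit$residual_df)
  )
  structure(
    list(
      slope = fit$slope, reference_value = reference_value,
      se = fit$se_slope, t_statistic = t_stat, df = fit$residual_df,
      p_value = min(p, 1), direction = direction, fit = fit
    ),
    class = "slope_test"
  )
}

#' Compare the slopes of two regression lines
#'
#' Pooled-model test of slope equality between two independently fitted
#' lines ("comparison of regression lines"): the slope difference is divided
#' by its standard error computed from the pooled residual variance of the
#' two separate fits, with n1 + n2 - 4 df. Algebraically identical to the
#' interaction-term t-test in the dummy-variable regression
#' `y ~ x * group`.
#'
#' @param x1,y1 First data set.
#' @param x2,y2 Second data set.
#' @param direction Sidedness of the test (default two-sided).
#' @return A `slope_test` with `slope` = slope1 - slope2 and reference 0.
#' @export
compare_regression_lines <- function(x1, y1, x2, y2,
                                     direction = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  d1 <- check_xy(x1, y1)
  d2 <- check_xy(x2, y2)
  f1 <- stats::lm(y ~ x, data = d1)
  f2 <- stats::lm(y ~ x, data = d2)
  b1 <- stats::coef(f1)[["x"]]
  b2 <- stats::coef(f2)[["x"]]
  n1 <- length(d1$x); n2 <- length(d2$x)
  df <- n1 + n2 - 4
  s2_pooled <- (sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)) / df
  sxx1 <- sum((d1$x - mean(d1$x))^2)
  sxx2 <- sum((d2$x - mean(d2$x))^2)
  se_diff <- sqrt(s2_pooled * (1 / sxx1 + 1 / sxx2))
  diff <- b1 - b2
  scale_ref <- max(abs(b1), abs(b2), 1)
  if (se_diff <= 1e-10 * scale_ref) {
    t_stat <- if (abs(diff) <= 1e-8 * scale_ref) 0 else sign(diff) * Inf
  } else {
    t_stat <- diff / se_diff
  }
  p <- switch(direction,
    two.sided = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
    greater = stats::pt(t_stat, df, lower.tail = FALSE),
    less = stats::pt(t_stat, df)
  )
  structure(
    list(
      slope = b1 - b2, reference_value = 0, se = se_diff,
      t_statistic = t_stat, df = df, p_value = min(p, 1),
      direction = direction,
      slope1 = b1, slope2 = b2
    ),
    class = "slope_test"
  )
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("Slope test vs %.4g (%s): t = %.4g on %d df, P = %.4g\n",
              x$reference_value, x$direction, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

# fast OLS slope/intercept for bootstrap resamples (no inference needed)
ols_coef <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - b * mx, slope = b)
}

#' C/N threshold: x-intercept of an enrichment regression
#'
#' The fitted line `enrichment = intercept + slope * C/N` crosses zero at
#' `-intercept/slope`; above this C/N ratio the model predicts essentially no
#' further tracer allocation to the symbiont. The point estimate is
#' accompanied by a percentile bootstrap confidence interval over
#' case-resampled refits. The threshold is only meaningful when the slope is
#' itself distinguishable from zero, so a non-significant slope is an error,
#' not a number.
#'
#' @inheritParams fit_linear
#' @param n_bootstrap Number of case resamples (default 2000).
#' @param seed Mandatory integer seed for the resampling.
#' @param level Confidence level (default 0.95).
#' @param alpha Significance gate on the slope (default 0.05).
#' @return A `threshold_estimate`: `x_intercept`, `ci_low`, `ci_high`,
#'   `n_bootstrap`, `seed`, plus the underlying `fit`.
#' @export
x_intercept_threshold <- function(x, y, n_bootstrap = 2000, seed, level = 0.95,
                                  alpha = 0.05) {
  if (missing(seed)) {
    stop_mycotrace("invalid_argument", "`seed` is mandatory for the bootstrap.")
  }
  fit <- fit_linear(x, y)
  if (fit$p_slope > alpha) {
    stop_mycotrace("threshold_undefined", sprintf(
      "Slope not significant (P = %.3g > %.2g): the x-intercept of a flat line is meaningless.",
      fit$p_slope, alpha
    ))
  }
  xv <- fit$x; yv <- fit$y; n <- fit$n
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), nrow = n)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    xi <- xv[idx[, b]]
    if (stats::var(xi) == 0) return(NA_real_)
    cf <- ols_coef(xi, yv[idx[, b]])
    if (cf[["slope"]] == 0) return(NA_real_)
    -cf[["intercept"]] / cf[["slope"]]
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(
    list(
      x_intercept = -fit$intercept / fit$slope,
      ci_low = qs[1], ci_high = qs[2],
      n_bootstrap = n_bootstrap, n_effective = length(boot),
      seed = seed, level = level, fit = fit
    ),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("x-intercept threshold: %.3f (%.0f%% bootstrap CI %.3f - %.3f, B = %d, seed %d)\n",
              x$x_intercept, 100 * x$level, x$ci_low, x$ci_high,
              x$n_bootstrap, x$seed))
  invisible(x)
}

#' Pearson correlation with significance test
#'
#' Wrapper around the exact t-based Pearson test
#' (`t = r * sqrt((n-2)/(1-r^2))` on n-2 df), returned as a one-row tibble.
#'
#' @inheritParams fit_linear
#' @return Tibble with `r`, `t_statistic`, `df`, `p_value`, `n`.
#' @export
pearson_correlation_test <- function(x, y) {
  xy <- check_xy(x, y)
  if (stats::var(xy$y) == 0) {
    stop_mycotrace("undefined_correlation", "y is constant; correlation undefined.")
  }
  ht <- stats::cor.test(xy$x, xy$y, method = "pearson")
  tibble::tibble(
    r = unname(ht$estimate),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n = length(xy$x)
  )
}

#' One-sided test of enrichment above non-labelled controls
#'
#' Welch two-sample t-test of labelled against control values. Under pulse
#' labeling the alternative is directional -- tissue enrichment can only sit
#' at or above natural abundance -- so the default is one-sided `"greater"`.
#'
#' @param labelled,control Numeric vectors, each with at least 2 values.
#' @param direction Alternative hypothesis (default `"greater"`).
#' @return Tibble with `t_statistic`, `df` (Welch-Satterthwaite), `p_value`,
#'   group means, and `direction`.
#' @export
enrichment_above_control_test <- function(labelled, control,
                                          direction = c("greater", "two.sided", "less")) {
  direction <- match.arg(direction)
  labelled <- labelled[is.finite(labelled)]
  control <- control[is.finite(control)]
  if (length(labelled) < 2 || length(control) < 2) {
    stop_mycotrace("invalid_argument",
                   "Both samples need at least 2 finite values.")
  }
  ht <- stats::t.test(labelled, control, alternative = direction, var.equal = FALSE)
  tibble::tibble(
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_labelled = mean(labelled),
    mean_control = mean(control),
    direction = direction
  )
}
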