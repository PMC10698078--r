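test_that("fit_linear recovers exact lines and rejects degenerate designs", {
  x <- 1:5
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r, 1, tolerance = 1e-10)

  fc <- fit_linear(x, rep(3, 5))
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r, 0)

  expect_error(fit_linear(rep(2, 5), 1:5),
               class = "mycotrace_error_degenerate_design")
  expect_error(fit_linear(1:2, 1:2), class = "mycotrace_error_degenerate_design")

  # parameter recovery at the study's generating values
  set.seed(101)
  slopes <- replicate(200, {
    cn <- runif(33, 7, 30)
    fit_linear(cn, 57.1 - 2.49 * cn + rnorm(33, 0, 5))$slope
  })
  expect_lt(abs(mean(slopes) + 2.49), 0.1)
})

test_that("slope test against a reference uses the t distribution on n-2 df", {
  x <- seq(0, 10, length.out = 12)
  st <- test_slope_against_value(x, x, reference_value = 1)
  expect_equal(st$t_statistic, 0)
  expect_equal(st$p_value, 1)

  set.seed(31)
  y <- 1.4 * x + rnorm(12, 0, 0.5)
  fit <- fit_linear(x, y)
  st2 <- test_slope_against_value(x, y, reference_value = 1)
  t_oracle <- (fit$slope - 1) / fit$se_slope
  expect_equal(st2$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(st2$p_value, 2 * pt(abs(t_oracle), 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # reference at the fitted slope itself gives p = 1
  st3 <- test_slope_against_value(x, y, reference_value = fit$slope)
  expect_equal(st3$p_value, 1, tolerance = 1e-12)
  # printed-style scenario: t = 2.556 on 23 df
  expect_equal(2 * pt((1.23 - 1) / 0.09, 23, lower.tail = FALSE),
               2 * pt(2.5556, 23, lower.tail = FALSE), tolerance = 1e-3)
})

test_that("comparison of regression lines equals the interaction-term regression", {
  # small fixture, printed in code
  x1 <- c(1, 2, 3, 4, 5, 6); y1 <- c(2.1, 4.3, 5.8, 8.4, 9.9, 12.2)
  x2 <- c(1, 2, 3, 4, 5, 6); y2 <- c(1.2, 1.9, 3.4, 3.8, 5.1, 5.6)
  res <- compare_regression_lines(x1, y1, x2, y2)
  # oracle: explicit dummy-variable OLS with interaction
  df <- data.frame(x = c(x1, x2), y = c(y1, y2),
                   g = rep(c(0, 1), each = 6))
  cf <- summary(lm(y ~ x * g, data = df))$coefficients
  expect_equal(abs(res$t_statistic), abs(cf["x:g", "t value"]), tolerance = 1e-9)
  expect_equal(res$p_value, cf["x:g", "Pr(>|t|)"], tolerance = 1e-9)
  expect_equal(res$df, 8)

  # identical sets: zero difference, p = 1
  same <- compare_regression_lines(x1, y1, x1, y1)
  expect_equal(same$slope, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  # exactly parallel noise-free lines: difference 0 even with zero residual SE
  par <- compare_regression_lines(x1, 2 * x1, x2, 2 * x2 + 5)
  expect_equal(par$slope, 0, tolerance = 1e-12)
  expect_equal(par$p_value, 1)
})

test_that("x-intercept threshold matches the printed-coefficient arithmetic", {
  cn <- seq(7, 30, length.out = 33)
  thr13 <- x_intercept_threshold(cn, 57.1 - 2.49 * cn, n_bootstrap = 200, seed = 1)
  expect_equal(thr13$x_intercept, 57.1 / 2.49, tolerance = 1e-9)
  thr15 <- x_intercept_threshold(cn, 15.1 - 0.57 * cn, n_bootstrap = 200, seed = 1)
  expect_equal(thr15$x_intercept, 15.1 / 0.57, tolerance = 1e-9)

  # exact line: the interval collapses onto the point estimate
  thr <- x_intercept_threshold(1:10, 10 - (1:10), n_bootstrap = 100, seed = 2)
  expect_equal(thr$x_intercept, 10)
  expect_equal(thr$ci_low, 10, tolerance = 1e-9)
  expect_equal(thr$ci_high, 10, tolerance = 1e-9)

  # a flat relationship has no meaningful threshold
  set.seed(8)
  expect_error(
    x_intercept_threshold(1:20, rnorm(20), n_bootstrap = 100, seed = 3),
    class = "mycotrace_error_threshold_undefined"
  )
})

test_that("threshold bootstrap CI is ordered around the estimate and seeded", {
  set.seed(12)
  cn <- runif(40, 7, 30)
  y <- 57.1 - 2.49 * cn + rnorm(40, 0, 5)
  a <- x_intercept_threshold(cn, y, n_bootstrap = 500, seed = 9)
  b <- x_intercept_threshold(cn, y, n_bootstrap = 500, seed = 9)
  expect_identical(a$ci_low, b$ci_low)
  expect_lte(a$ci_low, a$x_intercept)
  expect_gte(a$ci_high, a$x_intercept)
})

test_that("Pearson test reproduces the exact t-transform of r", {
  x <- 1:6
  expect_equal(pearson_correlation_test(x, 2 * x)$r, 1, tolerance = 1e-12)
  set.seed(14)
  xx <- rnorm(7); yy <- rnorm(7)
  res <- pearson_correlation_test(xx, yy)
  t_oracle <- res$r * sqrt((7 - 2) / (1 - res$r^2))
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(abs(t_oracle), 5, lower.tail = FALSE),
               tolerance = 1e-9)
  # the n = 7, r = 0.475 configuration gives p ~= 0.28
  t7 <- 0.475 * sqrt(5 / (1 - 0.475^2))
  expect_equal(round(2 * pt(t7, 5, lower.tail = FALSE), 3), 0.281)
  expect_error(pearson_correlation_test(rep(1, 5), 1:5),
               class = "mycotrace_error_degenerate_design")
})

test_that("Welch control test matches the hand-computed statistic", {
  lab <- c(4.1, 5.3, 6.2, 5.8, 4.9)
  con <- c(0.2, -0.1, 0.4, 0.05)
  res <- enrichment_above_control_test(lab, con, direction = "greater")
  s1 <- var(lab) / 5; s2 <- var(con) / 4
  t_hand <- (mean(lab) - mean(con)) / sqrt(s1 + s2)
  df_hand <- (s1 + s2)^2 / (s1^2 / 4 + s2^2 / 3)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p_value, pt(t_hand, df_hand, lower.tail = FALSE),
               tolerance = 1e-9)

  # identical samples sit at p ~ 0.5 one-sided; a large shift is decisive
  set.seed(3)
  a <- rnorm(20)
  expect_gt(enrichment_above_control_test(a, a)$p_value, 0.3)
  expect_lt(enrichment_above_control_test(a + 10, a)$p_value, 1e-3)
  expect_error(enrichment_above_control_test(1, c(1, 2)),
               class = "mycotrace_error_invalid_argument")
})

test_that("slope test holds its nominal size at the true slope", {
  set.seed(77)
  alpha <- 0.05
  n_sim <- 1000
  rejections <- replicate(n_sim, {
    x <- runif(25, 0, 10)
    y <- 1.5 * x + rnorm(25)
    test_slope_against_value(x, y, reference_value = 1.5)$p_value <= alpha
  })
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lt(abs(mean(rejections) - alpha), 2 * se + 1e-12)
})
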