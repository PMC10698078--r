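# letters must encode pairwise significance exactly: share a letter iff the
# adjusted p-value exceeds alpha
expect_letters_consistent <- function(res) {
  gs <- res$group_stats
  pw <- res$pairwise
  for (k in seq_len(nrow(pw))) {
    l1 <- strsplit(gs$letters[gs$group == pw$group1[k]], "")[[1]]
    l2 <- strsplit(gs$letters[gs$group == pw$group2[k]], "")[[1]]
    share <- length(intersect(l1, l2)) > 0
    if (pw$p_adj[k] <= res$alpha) {
      expect_false(share, label = sprintf(
        "significant pair %s-%s shares a letter", pw$group1[k], pw$group2[k]))
    } else {
      expect_true(share, label = sprintf(
        "non-significant pair %s-%s shares no letter", pw$group1[k], pw$group2[k]))
    }
  }
}

test_that("Tukey-Kramer adjusted p-values match the studentized-range oracle", {
  set.seed(5)
  d <- data.frame(
    g = rep(c("a", "b", "c"), times = c(5, 7, 6)),
    y = c(rnorm(5, 10), rnorm(7, 12), rnorm(6, 12.5))
  )
  res <- anova_tukey(d, "y", "g", log_transform = "never")

  # oracle: direct studentized-range evaluation from group summaries
  fit <- aov(y ~ g, data = d)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfr <- summary(fit)[[1]]["Residuals", "Df"]
  means <- tapply(d$y, d$g, mean)
  ns <- table(d$g)
  for (k in seq_len(nrow(res$pairwise))) {
    g1 <- res$pairwise$group1[k]; g2 <- res$pairwise$group2[k]
    q <- abs(means[g1] - means[g2]) / sqrt(mse / 2 * (1 / ns[g1] + 1 / ns[g2]))
    p_oracle <- ptukey(q, nmeans = 3, df = dfr, lower.tail = FALSE)
    expect_equal(res$pairwise$p_adj[k], unname(p_oracle), tolerance = 1e-6)
  }

  # independent cross-check against stats::TukeyHSD
  hsd <- TukeyHSD(fit)$g
  key <- paste(res$pairwise$group2, res$pairwise$group1, sep = "-")
  expect_equal(res$pairwise$p_adj, unname(hsd[key, "p adj"]), tolerance = 1e-6)
  expect_letters_consistent(res)
})

test_that("letters separate clear effects and unite homogeneous groups", {
  set.seed(8)
  strong <- data.frame(
    g = rep(c("lo", "hi"), each = 8),
    y = c(rnorm(8, 0, 0.5), rnorm(8, 10, 0.5))
  )
  res <- anova_tukey(strong, "y", "g", log_transform = "never")
  gs <- res$group_stats
  expect_false(gs$letters[1] == gs$letters[2])
  expect_lt(res$p_value, 1e-6)

  same <- data.frame(g = rep(c("a", "b", "c"), each = 10), y = rnorm(30))
  res2 <- anova_tukey(same, "y", "g", log_transform = "never")
  expect_letters_consistent(res2)

  # mixed pattern: a < b ~ c with b,c overlapping
  set.seed(15)
  mixed <- data.frame(
    g = rep(c("a", "b", "c"), each = 12),
    y = c(rnorm(12, 0), rnorm(12, 3), rnorm(12, 3.4))
  )
  expect_letters_consistent(anova_tukey(mixed, "y", "g", log_transform = "never"))

  expect_error(anova_tukey(data.frame(g = c("a", "a", "b"), y = 1:3), "y", "g"),
               class = "mycotrace_error_degenerate_group")
})

test_that("Shapiro-Wilk gate triggers the log transform on skewed data", {
  set.seed(22)
  skewed <- data.frame(
    g = rep(c("a", "b"), each = 20),
    y = exp(c(rnorm(20, 1, 1), rnorm(20, 2, 1)))
  )
  auto <- anova_tukey(skewed, "y", "g", log_transform = "auto")
  expect_true(auto$log_transformed)
  expect_true("mean_backtransformed" %in% names(auto$group_stats))
  never <- anova_tukey(skewed, "y", "g", log_transform = "never")
  expect_false(never$log_transformed)
})

test_that("two-way block ANOVA matches a hand sums-of-squares decomposition", {
  # balanced fixture: 3 tissues x 2 dates x 2 replicates
  d <- data.frame(
    tissue = rep(rep(c("FR", "CR", "EM"), each = 2), times = 2),
    time = rep(c(5, 20), each = 6),
    y = c(4.2, 4.8, 7.1, 6.9, 11.3, 10.7,
          4.6, 5.1, 7.4, 7.0, 11.8, 11.1)
  )
  res <- two_way_block_anova(d, "y", "tissue", "time")

  # oracle: type-I SS computed from group means on the balanced design
  grand <- mean(d$y)
  ss_tissue <- sum(4 * (tapply(d$y, d$tissue, mean) - grand)^2)
  ss_time <- sum(6 * (tapply(d$y, d$time, mean) - grand)^2)
  ss_total <- sum((d$y - grand)^2)
  ss_resid <- ss_total - ss_tissue - ss_time
  expect_equal(res$sumsq[res$term == "tissue"], ss_tissue, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "time"], ss_time, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "Residuals"], ss_resid, tolerance = 1e-9)
  f_tissue <- (ss_tissue / 2) / (ss_resid / 8)
  expect_equal(res$f_statistic[res$term == "tissue"], f_tissue, tolerance = 1e-9)

  # tissue-only effect: significant tissue term, unremarkable time term
  set.seed(30)
  d2 <- data.frame(
    tissue = rep(c("FR", "CR", "EM"), each = 10),
    time = rep(c(5, 20), times = 15),
    y = rep(c(0, 5, 10), each = 10) + rnorm(30)
  )
  res2 <- two_way_block_anova(d2, "y", "tissue", "time")
  expect_lt(res2$p_value[res2$term == "tissue"], 1e-6)
  expect_gt(res2$p_value[res2$term == "time"], 0.05)

  d3 <- d[d$tissue != "FR" | d$time != 5, ]
  expect_error(two_way_block_anova(d3, "y", "tissue", "time"),
               class = "mycotrace_error_unbalanced_design")
})
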