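#' One-way ANOVA with Tukey-Kramer letters
#'
#' Fixed-effects one-way ANOVA followed by Tukey-Kramer pairwise comparisons
#' (the unbalanced-n generalization of Tukey's HSD) and a compact letter
#' display. For groups i, j the studentized-range statistic is
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, referred to the
#' studentized-range distribution with k groups and the ANOVA residual df.
#'
#' Residual normality is screened with a Shapiro-Wilk test when
#' `log_transform = "auto"`: at p < 0.05 the response is log-transformed
#' (requires strictly positive values) and the analysis rerun; the output
#' records the scale actually used. The letter display is built by the
#' insert-and-absorb algorithm with groups ordered by descending mean, so
#' two groups share a letter if and only if their adjusted p exceeds `alpha`.
#'
#' @param data Data frame holding the response and grouping columns.
#' @param value Name of the response column (string).
#' @param group Name of the grouping column (string).
#' @param alpha Family significance level for the letters (default 0.05).
#' @param log_transform `"auto"` (Shapiro-Wilk gate), `"never"`, or
#'   `"always"`.
#' @return An `anova_tukey` object: `f_statistic`, `p_value`, `df` (term,
#'   residual), `group_stats` (mean, se, n, letters; means on the analysis
#'   scale with back-transformed means added when logged), `pairwise`
#'   (adjusted p per pair), `alpha`, `log_transformed`.
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05,
                        log_transform = c("auto", "never", "always")) {
  log_transform <- match.arg(log_transform)
  check_columns(data, c(value, group), "ANOVA input")
  df <- tibble::tibble(
    y = data[[value]],
    g = factor(data[[group]])
  ) |> dplyr::filter(is.finite(.data$y))
  counts <- table(df$g)
  counts <- counts[counts > 0]
  if (length(counts) < 2 || any(counts < 2)) {
    stop_mycotrace("degenerate_group",
                   "Need >= 2 groups with >= 2 observations each.")
  }
  df$g <- droplevels(df$g)

  run_aov <- function(y) {
    fit <- stats::aov(y ~ g, data = transform(df, y = y))
    list(fit = fit, resid = stats::resid(fit))
  }

  logged <- FALSE
  y_use <- df$y
  if (log_transform == "always") {
    logged <- TRUE
  } else if (log_transform == "auto") {
    res <- run_aov(df$y)$resid
    n_res <- length(res)
    if (n_res >= 3 && n_res <= 5000 && stats::sd(res) > 0) {
      sw <- stats::shapiro.test(res)
      logged <- sw$p.value < 0.05
    }
  }
  if (logged) {
    if (any(df$y <= 0)) {
      warn("Non-positive values: log transform skipped despite non-normal residuals.")
      logged <- FALSE
    } else {
      y_use <- log(df$y)
    }
  }

  fit <- stats::aov(y_use ~ g, data = transform(df, y_use = y_use))
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_resid <- an["Residuals", "Df"]
  k <- nlevels(df$g)

  stats_tbl <- tibble::tibble(group = levels(df$g)) |>
    dplyr::mutate(
      n = as.integer(table(df$g)[.data$group]),
      mean = as.numeric(tapply(y_use, df$g, mean)[.data$group]),
      se = sqrt(mse / .data$n)
    )
  if (logged) {
    stats_tbl$mean_backtransformed <- exp(stats_tbl$mean)
  }

  pairs <- utils::combn(levels(df$g), 2)
  pairwise <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ]
  ) |>
    dplyr::mutate(
      diff = stats_tbl$mean[match(.data$group1, stats_tbl$group)] -
        stats_tbl$mean[match(.data$group2, stats_tbl$group)],
      se = sqrt(mse / 2 * (
        1 / stats_tbl$n[match(.data$group1, stats_tbl$group)] +
          1 / stats_tbl$n[match(.data$group2, stats_tbl$group)]
      )),
      q = abs(.data$diff) / .data$se,
      p_adj = stats::ptukey(.data$q, nmeans = k, df = df_resid, lower.tail = FALSE)
    )

  letters_map <- compact_letter_display(
    groups = stats_tbl$group,
    means = stats_tbl$mean,
    significant = pairwise$p_adj <= alpha,
    pair1 = pairwise$group1, pair2 = pairwise$group2
  )
  stats_tbl$letters <- letters_map[stats_tbl$group]

  structure(
    list(
      f_statistic = an["g", "F value"],
      p_value = an["g", "Pr(>F)"],
      df = c(term = an["g", "Df"], residual = df_resid),
      group_stats = stats_tbl,
      pairwise = pairwise,
      alpha = alpha,
      log_transformed = logged
    ),
    class = "anova_tukey"
  )
}

# Insert-and-absorb compact letter display. Groups are ordered by descending
# mean before letters are assigned, so output is deterministic; groups share
# a letter iff no significant pair separates them.
compact_letter_display <- function(groups, means, significant, pair1, pair2) {
  ord <- order(-means)
  groups_sorted <- groups[ord]
  cols <- list(groups_sorted)  # start: one column holding every group
  sig_pairs <- which(significant)
  for (s in sig_pairs) {
    a <- pair1[s]; b <- pair2[s]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column contained in another (first copy wins on ties)
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i == j || !keep[i]) next
        if (all(new_cols[[i]] %in% new_cols[[j]])) {
          strict <- !all(new_cols[[j]] %in% new_cols[[i]])
          if (strict || j < i) {
            keep[i] <- FALSE
            break
          }
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the position of their top-most group, then letter them
  first_pos <- vapply(cols, function(col) min(match(col, groups_sorted)), numeric(1))
  cols <- cols[order(first_pos)]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    letter <- letters[i]
    for (g in cols[[i]]) out[g] <- paste0(out[g], letter)
  }
  out
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, P = %.4g%s\n",
              x$df[["term"]], x$df[["residual"]], x$f_statistic, x$p_value,
              if (x$log_transformed) " (log scale)" else ""))
  print(x$group_stats, ...)
  invisible(x)
}

#' Two-way fixed-effects ANOVA with a blocking factor
#'
#' Additive two-way ANOVA `response ~ tissue + time` (no interaction by
#' default), used to test compartment effects while accounting for sampling
#' date as a fixed block. With only two dates a random date effect is not
#' estimable, and the usual practice of pooling dates once the time term is
#' non-significant makes the fixed-block version operationally equivalent.
#'
#' @param data Data frame with response and the two factor columns.
#' @param response,factor_tissue,factor_time Column names (strings).
#' @param interaction Include the interaction term? Default `FALSE`.
#' @return Tidy tibble: one row per term with `df`, `sumsq`, `meansq`,
#'   `f_statistic`, `p_value` (sequential/type-I sums of squares).
#' @export
two_way_block_anova <- function(data, response, factor_tissue, factor_time,
                                interaction = FALSE) {
  check_columns(data, c(response, factor_tissue, factor_time), "ANOVA input")
  df <- tibble::tibble(
    y = data[[response]],
    tissue = factor(data[[factor_tissue]]),
    time = factor(data[[factor_time]])
  ) |> dplyr::filter(is.finite(.data$y))
  cells <- table(df$tissue, df$time)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_mycotrace("unbalanced_design", sprintf(
      paste0("Empty design cell(s): %s. Every tissue x time combination needs ",
             "at least one observation; drop the missing level or pool dates."),
      paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
            sep = ":", collapse = ", ")
    ))
  }
  form <- if (interaction) y ~ tissue * time else y ~ tissue + time
  an <- stats::anova(stats::aov(form, data = df))
  tibble::tibble(
    term = sub("tissue", factor_tissue,
               sub("time", factor_time, trimws(rownames(an)))),
    df = an$Df,
    sumsq = an$`Sum Sq`,
    meansq = an$`Mean Sq`,
    f_statistic = an$`F value`,
    p_value = an$`Pr(>F)`
  )
}
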