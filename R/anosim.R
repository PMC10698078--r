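#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether community composition differs
#' between a priori groups (here: sampling dates). All pairwise Bray-Curtis
#' dissimilarities are ranked jointly (midranks for ties); the statistic
#'
#'   R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)
#'
#' lies in `[-1, 1]`: 1 when every between-group pair is more dissimilar than
#' every within-group pair, about 0 under random labelling. Significance is
#' assessed by shuffling group labels; the reported p-value is
#' `(1 + #{R_perm >= R_obs}) / (n_permutations + 1)`, so it can never fall
#' below `1/(n_permutations + 1)`.
#'
#' @param comm Plants-by-species abundance matrix (matrix or data frame of
#'   numeric columns; drop identifier columns first, e.g. with
#'   `dplyr::select(-plant_id, -time_point)`), or a precomputed `dist`.
#' @param groups Group label per row of `comm`; at least 2 groups with at
#'   least 2 members each.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Integer seed driving the permutations; mandatory, recorded in
#'   the result, so a report can be reproduced exactly.
#' @return An object of class `anosim_result`: list with `r_statistic`,
#'   `p_value`, `n_permutations`, `seed`, `n`, `groups`, and the permuted
#'   statistics `perm_r`.
#' @examples
#' comm <- rbind(diag(3), diag(3))
#' anosim(comm, groups = rep(c("a", "b"), each = 3), n_permutations = 99, seed = 1)
#' @export
anosim <- function(comm, groups, n_permutations = 9999, seed) {
  if (missing(seed)) {
    stop_mycotrace("invalid_argument",
                   "`seed` is mandatory so permutation results are reproducible.")
  }
  d <- if (inherits(comm, "dist")) comm else bray_curtis_dissimilarity(comm)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop_mycotrace("invalid_argument",
                   "`groups` must have one label per row of `comm`.")
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop_mycotrace("degenerate_group",
                   "ANOSIM needs >= 2 groups with >= 2 members each.")
  }

  ranks <- rank(as.vector(d))  # midranks for ties
  # lower-triangle pair indices matching as.vector(dist)
  pair_i <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  denom <- n * (n - 1) / 4

  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(ranks[!within]) - mean(ranks[within])) / denom
  }

  r_obs <- r_stat(groups)
  set.seed(seed)
  perm_r <- vapply(seq_len(n_permutations), function(k) {
    r_stat(sample(groups))
  }, numeric(1))
  p <- (1 + sum(perm_r >= r_obs)) / (n_permutations + 1)

  structure(
    list(
      r_statistic = r_obs, p_value = p,
      n_permutations = n_permutations, seed = seed,
      n = n, groups = groups, perm_r = perm_r
    ),
    class = "anosim_result"
  )
}

#' Exhaustive-enumeration ANOSIM p-value
#'
#' Computes the exact permutation p-value by enumerating every distinct
#' assignment of the observed group sizes to the samples. Feasible only for
#' small n (the number of assignments is multinomial in the group sizes);
#' intended as the exact counterpart to the sampled p-value of [anosim()].
#'
#' @inheritParams anosim
#' @return List with `r_statistic`, `p_value`, `n_assignments`.
#' @export
anosim_exact <- function(comm, groups) {
  d <- if (inherits(comm, "dist")) comm else bray_curtis_dissimilarity(comm)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(unique(groups)) != 2) {
    stop_mycotrace("invalid_argument",
                   "Exhaustive enumeration implemented for two groups.")
  }
  ranks <- rank(as.vector(d))
  pair_i <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  denom <- n * (n - 1) / 4
  lev <- levels(groups)
  n1 <- sum(groups == lev[1])
  combos <- utils::combn(n, n1)

  r_for <- function(members1) {
    g <- rep(2L, n)
    g[members1] <- 1L
    within <- g[pair_i] == g[pair_j]
    (mean(ranks[!within]) - mean(ranks[within])) / denom
  }
  r_obs <- r_for(which(groups == lev[1]))
  all_r <- apply(combos, 2, r_for)
  list(
    r_statistic = r_obs,
    p_value = mean(all_r >= r_obs - 1e-12),
    n_assignments = ncol(combos)
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM (Bray-Curtis ranks)\n")
  cat(sprintf("  n = %d samples, %d groups\n", x$n, nlevels(x$groups)))
  cat(sprintf("  R = %.4f, P = %.4g (%d permutations, seed %d)\n",
              x$r_statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
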