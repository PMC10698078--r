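#' Mycorrhizal colonization rate
#'
#' Percentage of vital root tips that carry a fungal mantle:
#' `100 * vital_myco / (vital_myco + vital_nonmyco)`. Dry tips are excluded
#' from the denominator -- they are scored separately by [vitality_rate()].
#'
#' @param n_vital_myco,n_vital_nonmyco Non-negative tip counts (vectorized).
#' @return Colonization rate in percent.
#' @export
colonization_rate <- function(n_vital_myco, n_vital_nonmyco) {
  check_number(n_vital_myco, "n_vital_myco", lower = 0, class = "invalid_census")
  check_number(n_vital_nonmyco, "n_vital_nonmyco", lower = 0, class = "invalid_census")
  vital <- n_vital_myco + n_vital_nonmyco
  if (any(vital == 0)) {
    stop_mycotrace("undefined_rate",
                   "Colonization rate undefined: no vital root tips counted.")
  }
  100 * n_vital_myco / vital
}

#' Root-tip vitality rate
#'
#' Percentage of counted tips that are alive (mycorrhizal or not):
#' `100 * (vital_myco + vital_nonmyco) / (vital_myco + vital_nonmyco + dry)`.
#'
#' @inheritParams colonization_rate
#' @param n_dry Non-negative count of dry (dead) tips.
#' @return Vitality in percent.
#' @export
vitality_rate <- function(n_vital_myco, n_vital_nonmyco, n_dry) {
  check_number(n_vital_myco, "n_vital_myco", lower = 0, class = "invalid_census")
  check_number(n_vital_nonmyco, "n_vital_nonmyco", lower = 0, class = "invalid_census")
  check_number(n_dry, "n_dry", lower = 0, class = "invalid_census")
  total <- n_vital_myco + n_vital_nonmyco + n_dry
  if (any(total == 0)) {
    stop_mycotrace("undefined_rate",
                   "Vitality rate undefined: no root tips counted.")
  }
  100 * (n_vital_myco + n_vital_nonmyco) / total
}

#' Per-plant census indices
#'
#' Adds colonization and vitality percentages to a root-tip census table.
#'
#' @param census Tibble with columns `plant_id, time_point, n_vital_myco,
#'   n_vital_nonmyco, n_dry`.
#' @return The census with `colonization_pct` and `vitality_pct` appended.
#' @export
census_rates <- function(census) {
  check_columns(census, c("plant_id", "time_point", "n_vital_myco",
                          "n_vital_nonmyco", "n_dry"), "census table")
  census |>
    tibble::as_tibble() |>
    dplyr::mutate(
      colonization_pct = colonization_rate(.data$n_vital_myco, .data$n_vital_nonmyco),
      vitality_pct = vitality_rate(.data$n_vital_myco, .data$n_vital_nonmyco, .data$n_dry)
    )
}

#' Relative abundance of fungal morphotypes
#'
#' For every plant, each species' tip count is divided by the plant's number
#' of vital mycorrhizal tips. Vital mycorrhizal tips not assigned to any
#' morphotype are retained as an explicit `"unclassified"` row rather than
#' silently renormalized away (renormalizing would distort downstream
#' Bray-Curtis comparisons).
#'
#' @param morphotypes Tibble with columns `plant_id, time_point, species,
#'   n_tips`.
#' @param census Census table as in [census_rates()].
#' @return Long tibble `plant_id, time_point, species, n_tips,
#'   rel_abundance` including the unclassified remainder.
#' @export
relative_abundance <- function(morphotypes, census) {
  check_columns(morphotypes, c("plant_id", "time_point", "species", "n_tips"),
                "morphotype table")
  check_columns(census, c("plant_id", "time_point", "n_vital_myco"),
                "census table")
  joined <- morphotypes |>
    tibble::as_tibble() |>
    dplyr::left_join(
      dplyr::select(census, "plant_id", "time_point", "n_vital_myco"),
      by = c("plant_id", "time_point")
    )
  if (any(is.na(joined$n_vital_myco))) {
    stop_mycotrace("inconsistent_census",
                   "Morphotype rows without a matching census row.")
  }
  if (any(joined$n_vital_myco <= 0)) {
    stop_mycotrace("undefined_rate",
                   "Relative abundance undefined: census with no vital mycorrhizal tips.")
  }
  totals <- joined |>
    dplyr::group_by(.data$plant_id, .data$time_point, .data$n_vital_myco) |>
    dplyr::summarise(classified = sum(.data$n_tips), .groups = "drop")
  over <- totals$classified > totals$n_vital_myco
  if (any(over)) {
    stop_mycotrace("inconsistent_census", sprintf(
      "Morphotype tip counts exceed vital mycorrhizal tips for plant(s): %s.",
      paste(unique(totals$plant_id[over]), collapse = ", ")
    ))
  }
  unclassified <- totals |>
    dplyr::transmute(
      .data$plant_id, .data$time_point,
      species = "unclassified",
      n_tips = .data$n_vital_myco - .data$classified,
      n_vital_myco = .data$n_vital_myco
    )
  dplyr::bind_rows(joined, unclassified) |>
    dplyr::mutate(rel_abundance = .data$n_tips / .data$n_vital_myco) |>
    dplyr::select(-"n_vital_myco") |>
    dplyr::arrange(.data$plant_id, .data$time_point)
}

#' Plants-by-species community matrix
#'
#' Pivots per-plant relative abundances to the wide layout used by
#' [anosim()] and ordination. Rows sum to at most 1; the unclassified column
#' (if kept) absorbs the remainder.
#'
#' @inheritParams relative_abundance
#' @param include_unclassified Keep the `"unclassified"` column? Default
#'   `TRUE` for bookkeeping; drop it (the default inside [anosim()] usage)
#'   when comparing named-species composition.
#' @param use_relative If `FALSE`, raw tip counts are returned instead of
#'   proportions.
#' @return Wide tibble: `plant_id`, `time_point`, one column per species.
#' @export
community_matrix <- function(morphotypes, census, include_unclassified = TRUE,
                             use_relative = TRUE) {
  long <- relative_abundance(morphotypes, census)
  if (!include_unclassified) {
    long <- dplyr::filter(long, .data$species != "unclassified")
  }
  value_col <- if (use_relative) "rel_abundance" else "n_tips"
  long |>
    dplyr::select("plant_id", "time_point", "species", dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(
      names_from = "species", values_from = dplyr::all_of(value_col),
      values_fill = 0
    )
}

#' Fungal tissue fraction of an ectomycorrhizal cross-section
#'
#' `100 * area_fungal / area_total`, the share of a root-tip cross-section
#' occupied by the hyphal mantle and Hartig net. Any consistent area unit.
#'
#' @param area_fungal,area_total Non-negative areas; `area_fungal` must not
#'   exceed `area_total`, and `area_total` must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
fungal_tissue_fraction <- function(area_fungal, area_total) {
  check_number(area_fungal, "area_fungal", lower = 0, class = "inconsistent_areas")
  check_number(area_total, "area_total", class = "inconsistent_areas")
  if (any(area_total <= 0)) {
    stop_mycotrace("inconsistent_areas", "area_total must be positive.")
  }
  if (any(area_fungal > area_total)) {
    stop_mycotrace("inconsistent_areas",
                   "area_fungal cannot exceed area_total.")
  }
  100 * area_fungal / area_total
}

#' Bray-Curtis similarity between two abundance profiles
#'
#' `1 - sum(|a_i - b_i|) / sum(a_i + b_i)`. Symmetric, 1 for identical
#' profiles, 0 for disjoint supports. The complement (dissimilarity) is a
#' semimetric, not a metric.
#'
#' @param a,b Non-negative abundance vectors over the same ordered species
#'   list; not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop_mycotrace("invalid_argument",
                   "Abundance vectors must have equal length (same species order).")
  }
  check_number(a, "a", lower = 0)
  check_number(b, "b", lower = 0)
  denom <- sum(a + b)
  if (denom == 0) {
    stop_mycotrace("undefined_similarity",
                   "Bray-Curtis undefined for two all-zero profiles.")
  }
  1 - sum(abs(a - b)) / denom
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise `1 - similarity` over the rows of a plants-by-species abundance
#' matrix, as a `dist` object.
#'
#' @param mat Numeric matrix or data frame of non-negative abundances, one
#'   row per plant (identifier columns must already be dropped).
#' @return A `dist` of Bray-Curtis dissimilarities.
#' @export
bray_curtis_dissimilarity <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop_mycotrace("invalid_argument", "Need at least two rows.")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - bray_curtis_similarity(mat[i, ], mat[j, ])
    }
  }
  stats::as.dist(d)
}
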