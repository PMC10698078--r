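study_table_specs <- list(
  measurements = list(
    file = "measurements.tsv",
    cols = readr::cols(
      plant_id = readr::col_character(), time_point = readr::col_integer(),
      compartment = readr::col_character(), species = readr::col_character(),
      dry_mass_g = readr::col_double(), element = readr::col_character(),
      element_mass_g = readr::col_double(), isotope_value = readr::col_double(),
      value_kind = readr::col_character(), is_control = readr::col_logical()
    )
  ),
  census = list(
    file = "census.tsv",
    cols = readr::cols(
      plant_id = readr::col_character(), time_point = readr::col_integer(),
      n_vital_myco = readr::col_integer(), n_vital_nonmyco = readr::col_integer(),
      n_dry = readr::col_integer()
    )
  ),
  morphotypes = list(
    file = "morphotypes.tsv",
    cols = readr::cols(
      plant_id = readr::col_character(), time_point = readr::col_integer(),
      species = readr::col_character(), n_tips = readr::col_integer()
    )
  ),
  areas = list(
    file = "areas.tsv",
    cols = readr::cols(
      species = readr::col_character(), area_fungal = readr::col_double(),
      area_total = readr::col_double()
    )
  ),
  tip_biomass = list(
    file = "tip_biomass.tsv",
    cols = readr::cols(
      species = readr::col_character(), tip_biomass_g = readr::col_double()
    )
  ),
  tip_totals = list(
    file = "tip_totals.tsv",
    cols = readr::cols(
      plant_id = readr::col_character(), time_point = readr::col_integer(),
      total_em_tips = readr::col_double()
    )
  ),
  biomass = list(
    file = "biomass.tsv",
    cols = readr::cols(
      plant_id = readr::col_character(), time_point = readr::col_integer(),
      fine_root_g = readr::col_double(), coarse_root_g = readr::col_double(),
      soil_g = readr::col_double()
    )
  )
)

#' Write a study's input tables as TSV files
#'
#' Serializes every table of a synthetic (or assembled) study into the
#' tab-separated UTF-8 layout [read_study()] expects, plus
#' `ground_truth.tsv` when the study carries one.
#'
#' @param study A `synthetic_study` or a named list with the study tables.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (name in names(study_table_specs)) {
    if (is.null(study[[name]])) next
    path <- file.path(dir, study_table_specs[[name]]$file)
    readr::write_tsv(study[[name]], path)
    paths <- c(paths, path)
  }
  if (!is.null(study$ground_truth)) {
    path <- file.path(dir, "ground_truth.tsv")
    readr::write_tsv(ground_truth_report(study), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read and validate a study from TSV files
#'
#' Loads the measurement, census, morphotype, area, tip-biomass, tip-total
#' and biomass tables from a directory, checks schemas (missing columns are
#' named), row-level constraints (positive dry masses, element mass within
#' dry mass, single isotope-value dialect), and referential integrity: every
#' ectomycorrhizal measurement's species must appear in the morphotype table
#' of the same plant, and every census row must contain at least one vital
#' tip.
#'
#' @param dir Directory holding the TSV files written by [write_study()].
#' @return A `study_dataset`: validated list of tibbles, with provenance
#'   (file paths and modification times) attached.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) {
    stop_mycotrace("missing_file", sprintf("Study directory not found: %s", dir))
  }
  tables <- list()
  for (name in names(study_table_specs)) {
    spec <- study_table_specs[[name]]
    path <- file.path(dir, spec$file)
    if (!file.exists(path)) {
      stop_mycotrace("missing_file", sprintf("Required file missing: %s", path))
    }
    tbl <- readr::read_tsv(path, col_types = spec$cols, progress = FALSE)
    expected <- names(spec$cols$cols)
    check_columns(tbl, expected, spec$file)
    tables[[name]] <- tbl
  }

  validate_measurements(tables$measurements)
  if (any(tables$census$n_vital_myco + tables$census$n_vital_nonmyco < 1)) {
    stop_mycotrace("invalid_census",
                   "Census rows without any vital root tip.")
  }

  em_meas <- tables$measurements |>
    dplyr::filter(.data$compartment == "EM", !.data$is_control)
  if (nrow(em_meas) > 0) {
    if (any(is.na(em_meas$species))) {
      stop_mycotrace("referential_integrity",
                     "EM measurements must carry a species label.")
    }
    unmatched <- dplyr::anti_join(
      em_meas, tables$morphotypes,
      by = c("plant_id", "time_point", "species")
    )
    if (nrow(unmatched) > 0) {
      stop_mycotrace("referential_integrity", sprintf(
        "EM measurement species absent from the morphotype census: %s.",
        paste(utils::head(unique(paste(unmatched$plant_id, unmatched$species)), 5),
              collapse = "; ")
      ))
    }
  }

  structure(
    c(tables, list(provenance = tibble::tibble(
      table = names(tables),
      path = vapply(study_table_specs[names(tables)],
                    function(s) s$file, character(1)),
      read_at = format(Sys.time(), tz = "UTC")
    ))),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Validated study dataset\n")
  for (nm in setdiff(names(x), "provenance")) {
    cat(sprintf("  %-13s %5d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
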