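#' Isotope system constants
#'
#' Reference heavy/light isotope ratios of the international standards that
#' anchor delta notation: VPDB for carbon (13C/12C = 0.0111802) and
#' atmospheric N2 ("AIR", 15N/14N = 0.0036765). Exactly two systems are
#' supported. Enrichment concentrations are reported in mg g-1 dry mass for
#' 13C and ug g-1 for 15N, matching the magnitudes typical of canopy pulse
#' labeling (per-mil-scale 15N signals would vanish in mg units).
#'
#' @param heavy_label `"13C"` or `"15N"` (an existing system object passes
#'   through unchanged).
#' @return A list of class `isotope_system` with fields `heavy_label`,
#'   `reference_ratio`, `enrichment_unit`, and `conc_factor` (multiplier
#'   taking the mg g-1 enrichment of [enrichment_concentration()] to the
#'   reporting unit: 1 for 13C, 1000 for 15N).
#' @examples
#' isotope_system("13C")$reference_ratio
#' @export
isotope_system <- function(heavy_label) {
  if (inherits(heavy_label, "isotope_system")) {
    return(heavy_label)
  }
  heavy_label <- as.character(heavy_label)
  sys <- switch(heavy_label,
    "13C" = list(
      heavy_label = "13C", reference_ratio = 0.0111802,
      enrichment_unit = "mg_per_g", amount_unit = "mg", conc_factor = 1
    ),
    "15N" = list(
      heavy_label = "15N", reference_ratio = 0.0036765,
      enrichment_unit = "ug_per_g", amount_unit = "ug", conc_factor = 1000
    ),
    stop_mycotrace(
      "unknown_isotope_system",
      sprintf("Unknown isotope system '%s' (supported: 13C, 15N).", heavy_label)
    )
  )
  structure(sys, class = "isotope_system")
}

#' Convert delta notation to heavy-atom fraction
#'
#' delta (per mil) expresses the sample heavy/light ratio R_sample relative to
#' the standard: R_sample = R_std * (delta/1000 + 1). The heavy-atom fraction
#' is R/(1+R), i.e. heavy atoms over all atoms of the element.
#'
#' @param delta_permil Delta value(s) in per mil; must exceed -1000 (at -1000
#'   the sample would contain no heavy isotope at all, which is the limit, not
#'   a measurable value -- exactly -1000 maps to fraction 0).
#' @param system `"13C"`, `"15N"`, or an [isotope_system()].
#' @return Heavy-atom fraction in `[0, 1)`, strictly increasing in delta.
#' @seealso [atom_fraction_to_delta()] for the inverse.
#' @export
delta_to_atom_fraction <- function(delta_permil, system) {
  system <- isotope_system(system)
  check_number(delta_permil, "delta_permil", lower = -1000,
               class = "invalid_isotope_value")
  r <- system$reference_ratio * (delta_permil / 1000 + 1)
  r / (1 + r)
}

#' Convert heavy-atom fraction back to delta notation
#'
#' @param atom_fraction Heavy-atom fraction(s) in `[0, 1)`.
#' @inheritParams delta_to_atom_fraction
#' @return Delta in per mil relative to the system's standard.
#' @export
atom_fraction_to_delta <- function(atom_fraction, system) {
  system <- isotope_system(system)
  check_number(atom_fraction, "atom_fraction", lower = 0, upper = 1,
               class = "invalid_isotope_value")
  if (any(atom_fraction >= 1)) {
    stop_mycotrace("invalid_isotope_value",
                   "atom_fraction must be < 1 to map back to a finite ratio.")
  }
  r <- atom_fraction / (1 - atom_fraction)
  (r / system$reference_ratio - 1) * 1000
}

#' Atom-percent excess (APE)
#'
#' The tracer signal net of natural abundance: heavy-atom fraction of the
#' labelled sample minus that of the non-labelled control, times 100.
#' Negative values (control above sample, possible through measurement noise)
#' are retained, not clipped -- clipping would bias compartment means upward.
#'
#' @param af_labelled,af_control Heavy-atom fractions in `[0, 1]`.
#' @return APE in percent; antisymmetric in its arguments.
#' @export
atom_percent_excess <- function(af_labelled, af_control) {
  check_number(af_labelled, "af_labelled", 0, 1, class = "invalid_isotope_value")
  check_number(af_control, "af_control", 0, 1, class = "invalid_isotope_value")
  (af_labelled - af_control) * 100
}

#' Enrichment concentration: newly acquired heavy isotope per g dry mass
#'
#' APE/100 of the element pool is new heavy isotope; scaling by the element
#' concentration (1000 * element_mass / dry_mass, mg g-1) gives the mass of
#' newly acquired heavy isotope per gram dry tissue, in mg g-1. For 15N the
#' pipeline reports ug g-1 (multiply by `isotope_system("15N")$conc_factor`).
#'
#' @param ape Atom-percent excess, percent.
#' @param element_mass Total element mass in the sample, g (12C+13C or 14N+15N).
#' @param dry_mass Sample dry mass, g; must be positive.
#' @return Enrichment concentration in mg per g dry mass.
#' @export
enrichment_concentration <- function(ape, element_mass, dry_mass) {
  check_number(dry_mass, "dry_mass", class = "invalid_sample")
  if (any(dry_mass <= 0)) {
    stop_mycotrace("invalid_sample", "dry_mass must be positive.")
  }
  check_number(element_mass, "element_mass", lower = 0, class = "invalid_sample")
  if (any(element_mass > dry_mass)) {
    stop_mycotrace("invalid_sample",
                   "element_mass cannot exceed dry_mass.")
  }
  check_number(ape, "ape")
  (ape / 100) * 1000 * element_mass / dry_mass
}

#' Heavy-isotope amount in a compartment
#'
#' Amount = per-gram enrichment concentration times compartment dry biomass.
#' Multi-compartment pools are sums of such terms (see [root_pool_amount()]).
#'
#' @param enrichment_conc Enrichment concentration (mass per g dry mass).
#' @param biomass Compartment dry biomass, g; non-negative.
#' @return Amount in the unit of `enrichment_conc` times grams (mg for 13C
#'   mg g-1 inputs, ug for 15N ug g-1 inputs).
#' @export
compartment_amount <- function(enrichment_conc, biomass) {
  check_number(biomass, "biomass", class = "invalid_sample")
  if (any(biomass < 0)) {
    stop_mycotrace("invalid_sample", "biomass must be non-negative.")
  }
  check_number(enrichment_conc, "enrichment_conc")
  enrichment_conc * biomass
}

measurement_columns <- c(
  "plant_id", "time_point", "compartment", "species", "dry_mass_g",
  "element", "element_mass_g", "isotope_value", "value_kind", "is_control"
)

validate_measurements <- function(measurements) {
  check_columns(measurements, measurement_columns, "measurement table")
  kinds <- unique(measurements$value_kind)
  if (!all(kinds %in% c("delta_permil", "atom_fraction"))) {
    stop_mycotrace("dialect", sprintf(
      "value_kind must be 'delta_permil' or 'atom_fraction'; found: %s.",
      paste(setdiff(kinds, c("delta_permil", "atom_fraction")), collapse = ", ")
    ))
  }
  if (length(kinds) > 1) {
    stop_mycotrace("dialect",
      "Mixed value_kind dialects in one measurement table; a table must be all delta_permil or all atom_fraction.")
  }
  bad_mass <- which(!is.finite(measurements$dry_mass_g) | measurements$dry_mass_g <= 0)
  if (length(bad_mass) > 0) {
    stop_mycotrace("invalid_sample", sprintf(
      "Non-positive dry_mass_g in measurement row(s): %s.",
      paste(utils::head(bad_mass, 5), collapse = ", ")
    ))
  }
  bad_elem <- which(measurements$element_mass_g < 0 |
                      measurements$element_mass_g > measurements$dry_mass_g)
  if (length(bad_elem) > 0) {
    stop_mycotrace("invalid_sample", sprintf(
      "element_mass_g outside [0, dry_mass_g] in row(s): %s.",
      paste(utils::head(bad_elem, 5), collapse = ", ")
    ))
  }
  bad_sys <- setdiff(unique(measurements$element), c("13C", "15N"))
  if (length(bad_sys) > 0) {
    stop_mycotrace("unknown_isotope_system", sprintf(
      "Unknown element label(s): %s.", paste(bad_sys, collapse = ", ")
    ))
  }
  invisible(measurements)
}

#' Compute atom-percent excess and enrichment for a measurement table
#'
#' The table-level workhorse of the isotope module. Converts isotope values to
#' heavy-atom fractions (from delta if needed), averages the non-labelled
#' control samples per compartment x isotope system to estimate natural
#' abundance, and derives, for every labelled row, APE, element concentration
#' and enrichment concentration. 13C enrichment is reported in mg g-1 dry
#' mass, 15N in ug g-1 (`enrichment_unit` column carries the tag).
#'
#' Controls are required for every (compartment, element) combination that
#' appears among labelled rows; mapping controls compartment-wise is the
#' least-assumption choice when the control design is unpaired. Negative APE
#' values are kept and flagged in `ape_negative`.
#'
#' @param measurements Tibble in the long measurement layout (columns
#'   `plant_id, time_point, compartment, species, dry_mass_g, element,
#'   element_mass_g, isotope_value, value_kind, is_control`), one dialect of
#'   `value_kind` per table.
#' @return A tibble with one row per labelled measurement: identifiers plus
#'   `atom_fraction`, `control_atom_fraction`, `ape`, `ape_negative`,
#'   `element_conc_mg_g`, `enrichment_conc`, `enrichment_unit`.
#' @export
compute_enrichment <- function(measurements) {
  validate_measurements(measurements)
  m <- tibble::as_tibble(measurements)
  kind <- m$value_kind[1]

  m$atom_fraction <- if (kind == "delta_permil") {
    vapply(seq_len(nrow(m)), function(i) {
      delta_to_atom_fraction(m$isotope_value[i], m$element[i])
    }, numeric(1))
  } else {
    check_number(m$isotope_value, "isotope_value", 0, 1,
                 class = "invalid_isotope_value")
    m$isotope_value
  }

  controls <- m |>
    dplyr::filter(.data$is_control) |>
    dplyr::group_by(.data$compartment, .data$element) |>
    dplyr::summarise(
      control_atom_fraction = mean(.data$atom_fraction),
      n_controls = dplyr::n(),
      .groups = "drop"
    )

  labelled <- dplyr::filter(m, !.data$is_control)
  needed <- dplyr::distinct(labelled, .data$compartment, .data$element)
  have <- dplyr::semi_join(needed, controls, by = c("compartment", "element"))
  if (nrow(have) < nrow(needed)) {
    missing <- dplyr::anti_join(needed, controls, by = c("compartment", "element"))
    stop_mycotrace("missing_controls", sprintf(
      "No control samples for: %s. APE cannot be computed.",
      paste(paste(missing$compartment, missing$element), collapse = "; ")
    ))
  }

  labelled |>
    dplyr::left_join(controls, by = c("compartment", "element")) |>
    dplyr::mutate(
      ape = atom_percent_excess(.data$atom_fraction, .data$control_atom_fraction),
      ape_negative = .data$ape < 0,
      element_conc_mg_g = 1000 * .data$element_mass_g / .data$dry_mass_g,
      conc_factor = ifelse(.data$element == "15N", 1000, 1),
      enrichment_conc = enrichment_concentration(
        .data$ape, .data$element_mass_g, .data$dry_mass_g
      ) * .data$conc_factor,
      enrichment_unit = ifelse(.data$element == "15N", "ug_per_g", "mg_per_g")
    ) |>
    dplyr::select(-"conc_factor", -"value_kind", -"is_control")
}
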