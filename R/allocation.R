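#' Ectomycorrhizal heavy-isotope pool of a plant
#'
#' Sums, over fungal species, enrichment concentration x dry biomass per root
#' tip x number of tips carrying that species. Tip numbers are relative
#' abundance times the plant's total number of ectomycorrhizal tips and are
#' kept real-valued internally (rounding a proportion of ~30,000 tips would
#' bias small species); `tips` in the per-species breakdown is reported
#' unrounded.
#'
#' @param entries Data frame with columns `enrichment_conc` (heavy-isotope
#'   mass per g dry tip mass), `tip_biomass_g` (g per tip) and
#'   `relative_abundance` (proportions summing to at most 1), one row per
#'   species.
#' @param total_tips Total number of vital ectomycorrhizal root tips on the
#'   plant; positive.
#' @return The pool amount (same mass unit as `enrichment_conc` x g, i.e. mg
#'   for 13C, ug for 15N), with attribute `"per_species"`: a tibble of each
#'   species' tip number and contribution.
#' @export
em_pool_amount <- function(entries, total_tips) {
  check_columns(entries, c("enrichment_conc", "tip_biomass_g", "relative_abundance"),
                "species pool table")
  check_number(total_tips, "total_tips", class = "invalid_argument")
  if (length(total_tips) != 1 || total_tips <= 0) {
    stop_mycotrace("invalid_argument", "total_tips must be a single positive count.")
  }
  check_number(entries$enrichment_conc, "enrichment_conc", lower = -Inf)
  check_number(entries$tip_biomass_g, "tip_biomass_g", lower = 0)
  check_number(entries$relative_abundance, "relative_abundance", lower = 0, upper = 1)
  if (sum(entries$relative_abundance) > 1 + 1e-6) {
    stop_mycotrace("inconsistent_community", sprintf(
      "Relative abundances sum to %.6f > 1.", sum(entries$relative_abundance)
    ))
  }
  per_species <- tibble::as_tibble(entries) |>
    dplyr::mutate(
      tips = .data$relative_abundance * total_tips,
      amount = .data$enrichment_conc * .data$tip_biomass_g * .data$tips
    )
  structure(sum(per_species$amount), per_species = per_species)
}

#' Root heavy-isotope pool (fine + coarse)
#'
#' Amount = fine-root enrichment x fine-root biomass + coarse-root enrichment
#' x coarse-root biomass; the two-compartment case of [compartment_amount()].
#'
#' @param fine_enr,coarse_enr Enrichment concentrations (per g dry mass).
#' @param fine_biomass,coarse_biomass Dry biomasses, g; non-negative.
#' @return Pool amount in enrichment-unit x g.
#' @export
root_pool_amount <- function(fine_enr, fine_biomass, coarse_enr, coarse_biomass) {
  compartment_amount(fine_enr, fine_biomass) +
    compartment_amount(coarse_enr, coarse_biomass)
}

#' Share of one pool in another
#'
#' `100 * part / whole`, e.g. the fraction of fine-root tracer carbon that
#' sits in the ectomycorrhizal compartment.
#'
#' @param part Non-negative amount.
#' @param whole Positive reference amount in the same unit.
#' @return Share in percent.
#' @export
pool_share <- function(part, whole) {
  check_number(part, "part", lower = 0, class = "undefined_share")
  check_number(whole, "whole", class = "undefined_share")
  if (any(whole <= 0)) {
    stop_mycotrace("undefined_share", "`whole` must be positive.")
  }
  100 * part / whole
}

#' Rhizosphere heavy-isotope amount
#'
#' Soil enrichment concentration times the dry mass of rhizosphere soil
#' recovered from the root system.
#'
#' @param enrichment_conc_soil Enrichment per g dry soil.
#' @param soil_dry_mass Dry soil mass, g; non-negative.
#' @return Amount in enrichment-unit x g.
#' @export
rhizosphere_amount <- function(enrichment_conc_soil, soil_dry_mass) {
  compartment_amount(enrichment_conc_soil, soil_dry_mass)
}

#' 13C/15N transfer ratio of a compartment
#'
#' Unit-harmonized mass ratio of newly acquired carbon to nitrogen: the 13C
#' amount (mg) is converted to ug before dividing by the 15N amount (ug).
#' A rising ratio along the transport path (roots to ectomycorrhizas)
#' indicates proportionally stronger carbon than nitrogen delivery to the
#' symbiont.
#'
#' @param amount_13c_mg Amount of new 13C, mg.
#' @param amount_15n_ug Amount of new 15N, ug; must be positive.
#' @return Unitless mass ratio.
#' @export
transfer_ratio <- function(amount_13c_mg, amount_15n_ug) {
  check_number(amount_13c_mg, "amount_13c_mg", lower = 0, class = "undefined_ratio")
  check_number(amount_15n_ug, "amount_15n_ug", class = "undefined_ratio")
  if (any(amount_15n_ug <= 0)) {
    stop_mycotrace("undefined_ratio", "15N amount must be positive.")
  }
  (amount_13c_mg * 1000) / amount_15n_ug
}
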