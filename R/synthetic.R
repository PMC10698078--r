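#' Configuration for the synthetic study generator
#'
#' Bundles every generating parameter of [simulate_study()] with defaults
#' that emulate the field conditions the pipeline is designed for: a young
#' beech root system carrying ~16 ectomycorrhizal species of which 7
#' dominants cover ~80% of vital tips, ~29,215 ectomycorrhizal tips per
#' plant, per-species carbon 380-440 mg g-1 with C/N ratios spanning 7-30,
#' 13C enrichment declining with C/N (slope -2.49 mg g-1 per C/N unit,
#' intercept 57.1), 15N enrichment declining more weakly (slope -0.57 ug g-1,
#' intercept 15.1), and ectomycorrhizal enrichment coupled to the attached
#' lateral rootlet with slopes 1.23 (13C) and 0.53 (15N). Two destructive
#' sampling dates (days 5 and 20) with no community shift between them.
#'
#' @param n_plants Labelled plants per sampling date (default 10).
#' @param n_controls Non-labelled control plants (default 10).
#' @param time_points Days since label start (default `c(5, 20)`).
#' @param n_species,n_dominant Species richness and number of dominant taxa.
#' @param dominant_share Expected summed abundance of dominant taxa (0.8).
#' @param dirichlet_concentration Total Dirichlet mass; larger values give
#'   more similar communities across plants (default 60).
#' @param total_tips_mean,total_tips_sd Total ectomycorrhizal tips per plant.
#' @param census_tips Root tips inspected per plant for the census (~400).
#' @param colonization_mean,colonization_sd Mycorrhizal colonization, percent.
#' @param vitality_mean,vitality_sd Root-tip vitality, percent.
#' @param cn_range Species-level C/N ratio range.
#' @param cn_jitter_sd Within-species (per-plant) C/N spread.
#' @param carbon_conc_range Ectomycorrhizal C concentration range, mg g-1.
#' @param nitrogen_conc_range Nominal N concentration range, mg g-1 (N is
#'   derived as C / (C/N); the configured range documents the target scale).
#' @param slope_13c,intercept_13c,noise_sd_13c 13C enrichment ~ C/N model
#'   (mg g-1 scale).
#' @param slope_15n,intercept_15n,noise_sd_15n 15N enrichment ~ C/N model
#'   (ug g-1 scale).
#' @param lateral_coupling_slope_13c,lateral_coupling_slope_15n Ratio of
#'   ectomycorrhizal to attached-lateral-root enrichment.
#' @param lateral_noise_sd_13c,lateral_noise_sd_15n Noise on the lateral-root
#'   side of the coupling.
#' @param control_delta_mean Named natural-abundance delta means, per mil.
#' @param control_delta_sd Instrumental spread of control deltas (0.5 per mil).
#' @param compartment_n_conc,compartment_c_conc Named element contents
#'   (mg g-1) per compartment.
#' @param compartment_enr_13c,compartment_enr_15n Mean enrichment of the
#'   bulk compartments (mg g-1 / ug g-1); back-solved from per-plant pool
#'   sizes of ~154 mg 13C (roots), ~27 mg (fine roots) and ~1.9 mg
#'   (rhizosphere) at the default biomasses.
#' @param compartment_enr_rel_sd Relative SD of compartment enrichments.
#' @param tip_biomass_range Dry biomass per root tip, g.
#' @param n_pooled_tips Tips pooled into one ectomycorrhizal sample.
#' @param fine_root_biomass_mean,fine_root_biomass_sd,coarse_root_biomass_mean,coarse_root_biomass_sd,soil_mass_mean,soil_mass_sd
#'   Per-plant compartment dry masses, g.
#' @param fungal_tissue_range Cross-section fungal tissue percentage range.
#' @param truncate_enrichment Rectify generated enrichments at zero (the
#'   physical floor of tracer uptake; default `TRUE`). When `FALSE`,
#'   enrichments stay Gaussian around the linear model (floored only at the
#'   natural-abundance limit), which is the mode parameter-recovery studies
#'   use; ground truth always keeps the unrectified values so rectification
#'   bias can be quantified.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_plants = 10,
    n_controls = 10,
    time_points = c(5L, 20L),
    n_species = 16,
    n_dominant = 7,
    dominant_share = 0.8,
    dirichlet_concentration = 60,
    total_tips_mean = 29215,
    total_tips_sd = 4361,
    census_tips = 400,
    colonization_mean = 92.6,
    colonization_sd = 2.2,
    vitality_mean = 89.6,
    vitality_sd = 2.1,
    cn_range = c(7, 30),
    cn_jitter_sd = 1,
    carbon_conc_range = c(380, 440),
    nitrogen_conc_range = c(20, 40),
    slope_13c = -2.49,
    intercept_13c = 57.1,
    noise_sd_13c = 5,
    slope_15n = -0.57,
    intercept_15n = 15.1,
    noise_sd_15n = 2,
    lateral_coupling_slope_13c = 1.23,
    lateral_coupling_slope_15n = 0.53,
    lateral_noise_sd_13c = 3,
    lateral_noise_sd_15n = 1.5,
    control_delta_mean = c("13C" = -28, "15N" = 0),
    control_delta_sd = 0.5,
    compartment_n_conc = c(BA = 8.75, CR = 6.41, FR = 12.34, LR = 15.69,
                           EM = 26.23, RS = 2.64),
    compartment_c_conc = c(BA = 448.1, CR = 452.7, FR = 344.3, LR = 471.0,
                           EM = 419.7, RS = 36.6),
    compartment_enr_13c = c(BA = 5, CR = 10.2, FR = 6.9, RS = 0.035),
    compartment_enr_15n = c(BA = 3, CR = 9.5, FR = 6.0, RS = 0.02),
    compartment_enr_rel_sd = 0.15,
    tip_biomass_range = c(1e-4, 4e-4),
    n_pooled_tips = 20,
    fine_root_biomass_mean = 3.9,
    fine_root_biomass_sd = 1.1,
    coarse_root_biomass_mean = 12.5,
    coarse_root_biomass_sd = 1.0,
    soil_mass_mean = 54,
    soil_mass_sd = 10,
    fungal_tissue_range = c(25, 50),
    truncate_enrichment = TRUE) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_dominant <= cfg$n_species,
    cfg$dominant_share > 0, cfg$dominant_share < 1,
    diff(cfg$cn_range) > 0, diff(cfg$carbon_conc_range) > 0,
    diff(cfg$tip_biomass_range) > 0,
    cfg$noise_sd_13c >= 0, cfg$noise_sd_15n >= 0,
    cfg$control_delta_sd >= 0,
    all(c("13C", "15N") %in% names(cfg$control_delta_mean))
  )
  structure(cfg, class = "simulation_config")
}

synthetic_species_names <- function(n_species, n_dominant) {
  dominant <- c("Pachyphlodes_conglomerata", "UEM1", "UEM2", "UEM3",
                "Tomentella_punicea", "Cenococcum_geophilum", "Tomentella_sp1")
  dominant <- dominant[seq_len(min(n_dominant, length(dominant)))]
  if (n_dominant > length(dominant)) {
    dominant <- c(dominant, sprintf("dom%02d", seq_len(n_dominant - length(dominant))))
  }
  rare <- sprintf("rare%02d", seq_len(n_species - n_dominant))
  c(dominant, rare)
}

# zero-rectification of generated enrichments (physical floor: tissue cannot
# lose more heavy isotope than natural abundance provides, so even the
# untruncated mode floors at APE = -100 * control atom fraction)
rectify <- function(x, truncate, floor = -Inf) {
  if (truncate) pmax(0, x) else pmax(floor, x)
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic ectomycorrhizal community
#'
#' Draws per-plant species abundances from a Dirichlet whose mass is
#' concentrated on the dominant taxa (so they jointly cover
#' `dominant_share` of tips in expectation), then assigns census and
#' morphotype tip counts consistent with the configured colonization and
#' vitality rates. Both sampling dates share the same community expectation
#' -- the generator deliberately builds in *no* community shift over time.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (mandatory; same seed + config gives identical
#'   tables).
#' @return List with `census`, `morphotypes`, `tip_totals` (total
#'   ectomycorrhizal tips per plant), `species` (names, dominance), and
#'   `abundance_expected` (the Dirichlet mean per species).
#' @export
generate_community <- function(config = simulation_config(), seed) {
  if (missing(seed)) stop_mycotrace("invalid_argument", "`seed` is mandatory.")
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)

  species <- synthetic_species_names(config$n_species, config$n_dominant)
  dominant <- seq_len(config$n_dominant)
  p_base <- numeric(config$n_species)
  p_base[dominant] <- config$dominant_share / config$n_dominant
  p_base[-dominant] <- (1 - config$dominant_share) / (config$n_species - config$n_dominant)
  alpha <- config$dirichlet_concentration * p_base

  plants <- tibble::tibble(
    plant_id = sprintf("P%02d", seq_len(config$n_plants * length(config$time_points))),
    time_point = rep(config$time_points, each = config$n_plants)
  )

  census_rows <- list()
  morpho_rows <- list()
  for (i in seq_len(nrow(plants))) {
    n_total <- max(50L, round(stats::rnorm(1, config$census_tips, config$census_tips * 0.05)))
    vit <- min(100, max(1, stats::rnorm(1, config$vitality_mean, config$vitality_sd)))
    col <- min(100, max(1, stats::rnorm(1, config$colonization_mean, config$colonization_sd)))
    n_vital <- stats::rbinom(1, n_total, vit / 100)
    n_myco <- stats::rbinom(1, n_vital, col / 100)
    census_rows[[i]] <- tibble::tibble(
      plant_id = plants$plant_id[i], time_point = plants$time_point[i],
      n_vital_myco = n_myco, n_vital_nonmyco = n_vital - n_myco,
      n_dry = n_total - n_vital
    )
    abund <- rdirichlet_one(alpha)
    counts <- as.integer(stats::rmultinom(1, n_myco, abund))
    morpho_rows[[i]] <- tibble::tibble(
      plant_id = plants$plant_id[i], time_point = plants$time_point[i],
      species = species, n_tips = counts
    ) |> dplyr::filter(.data$n_tips > 0)
  }

  tip_totals <- plants |>
    dplyr::mutate(total_em_tips = pmax(
      1000, round(stats::rnorm(dplyr::n(), config$total_tips_mean, config$total_tips_sd))
    ))

  list(
    census = dplyr::bind_rows(census_rows),
    morphotypes = dplyr::bind_rows(morpho_rows),
    tip_totals = tip_totals,
    species = tibble::tibble(
      species = species,
      dominant = seq_along(species) %in% dominant
    ),
    abundance_expected = setNames(p_base, species)
  )
}

#' Generate isotope measurements for a synthetic community
#'
#' Inverts the analysis chain: species-level C/N ratios are drawn uniformly
#' from `cn_range`, true enrichments follow the configured linear models in
#' C/N (Gaussian noise, rectified at zero), lateral-root enrichment is the
#' ectomycorrhizal value divided by the coupling slope plus noise, and bulk
#' compartments get configured mean enrichments. Every true enrichment is
#' then pushed backwards through APE and atom fraction to emit delta values,
#' so running the measurement table through [compute_enrichment()] recovers
#' the generating quantities (exactly when all noise SDs are zero).
#' Non-labelled control plants are generated at natural-abundance delta.
#'
#' @param community Output of [generate_community()].
#' @param config The same [simulation_config()].
#' @param seed Integer seed.
#' @return List with `measurements` (long measurement tibble, delta dialect)
#'   and `truth` (per plant x species generating values, including the
#'   unrectified enrichments, plus per-compartment true enrichments).
#' @export
generate_isotope_measurements <- function(community, config = simulation_config(), seed) {
  if (missing(seed)) stop_mycotrace("invalid_argument", "`seed` is mandatory.")
  set.seed(seed)

  species_tbl <- community$species |>
    dplyr::mutate(
      cn_species = stats::runif(dplyr::n(), config$cn_range[1], config$cn_range[2]),
      c_conc_species = stats::runif(dplyr::n(), config$carbon_conc_range[1],
                                    config$carbon_conc_range[2]),
      tip_biomass_g = stats::runif(dplyr::n(), config$tip_biomass_range[1],
                                   config$tip_biomass_range[2])
    )

  af_control <- vapply(c("13C", "15N"), function(el) {
    delta_to_atom_fraction(config$control_delta_mean[[el]], el)
  }, numeric(1))

  # ectomycorrhizal and lateral-root observations: dominant species only
  # (rare taxa yield too little material for isotope-ratio analysis)
  em <- community$morphotypes |>
    dplyr::inner_join(dplyr::filter(species_tbl, .data$dominant),
                      by = "species") |>
    dplyr::mutate(
      cn = pmax(1.5, .data$cn_species + stats::rnorm(dplyr::n(), 0, config$cn_jitter_sd)),
      c_conc = pmax(100, .data$c_conc_species + stats::rnorm(dplyr::n(), 0, 5)),
      n_conc = .data$c_conc / .data$cn,
      enr_13c_raw = config$intercept_13c + config$slope_13c * .data$cn +
        stats::rnorm(dplyr::n(), 0, config$noise_sd_13c),
      enr_13c = rectify(.data$enr_13c_raw, config$truncate_enrichment,
                        floor = -0.99 * af_control[["13C"]] * .data$c_conc),
      enr_15n_raw = config$intercept_15n + config$slope_15n * .data$cn +
        stats::rnorm(dplyr::n(), 0, config$noise_sd_15n),
      enr_15n = rectify(.data$enr_15n_raw, config$truncate_enrichment,
                        floor = -0.99 * af_control[["15N"]] * .data$n_conc * 1000),
      lr_13c = rectify(.data$enr_13c / config$lateral_coupling_slope_13c +
                         stats::rnorm(dplyr::n(), 0, config$lateral_noise_sd_13c),
                       config$truncate_enrichment,
                       floor = -0.99 * af_control[["13C"]] * 400),
      lr_15n = rectify(.data$enr_15n / config$lateral_coupling_slope_15n +
                         stats::rnorm(dplyr::n(), 0, config$lateral_noise_sd_15n),
                       config$truncate_enrichment,
                       floor = -0.99 * af_control[["15N"]] * 15 * 1000),
      em_dry_mass = config$n_pooled_tips * .data$tip_biomass_g,
      lr_dry_mass = stats::runif(dplyr::n(), 5e-4, 1.5e-3),
      lr_c_conc = pmax(100, stats::rnorm(dplyr::n(), config$compartment_c_conc[["LR"]], 10)),
      lr_n_conc = pmax(1, stats::rnorm(dplyr::n(), config$compartment_n_conc[["LR"]], 1))
    )

  # enrichment (reporting units) -> APE -> labelled atom fraction -> delta
  to_delta <- function(enr, conc_mg_g, element) {
    enr_mg <- if (element == "15N") enr / 1000 else enr
    ape <- 100 * enr_mg / conc_mg_g
    af <- pmax(af_control[[element]] + ape / 100, 1e-12)
    atom_fraction_to_delta(af, element)
  }

  em_rows <- dplyr::bind_rows(
    em |> dplyr::transmute(
      .data$plant_id, .data$time_point, compartment = "EM", .data$species,
      dry_mass_g = .data$em_dry_mass, element = "13C",
      element_mass_g = .data$c_conc / 1000 * .data$em_dry_mass,
      isotope_value = to_delta(.data$enr_13c, .data$c_conc, "13C")
    ),
    em |> dplyr::transmute(
      .data$plant_id, .data$time_point, compartment = "EM", .data$species,
      dry_mass_g = .data$em_dry_mass, element = "15N",
      element_mass_g = .data$n_conc / 1000 * .data$em_dry_mass,
      isotope_value = to_delta(.data$enr_15n, .data$n_conc, "15N")
    ),
    em |> dplyr::transmute(
      .data$plant_id, .data$time_point, compartment = "LR", .data$species,
      dry_mass_g = .data$lr_dry_mass, element = "13C",
      element_mass_g = .data$lr_c_conc / 1000 * .data$lr_dry_mass,
      isotope_value = to_delta(.data$lr_13c, .data$lr_c_conc, "13C")
    ),
    em |> dplyr::transmute(
      .data$plant_id, .data$time_point, compartment = "LR", .data$species,
      dry_mass_g = .data$lr_dry_mass, element = "15N",
      element_mass_g = .data$lr_n_conc / 1000 * .data$lr_dry_mass,
      isotope_value = to_delta(.data$lr_15n, .data$lr_n_conc, "15N")
    )
  )

  # bulk compartments (bark, coarse/fine root, rhizosphere soil)
  bulk_comps <- names(config$compartment_enr_13c)
  plants <- dplyr::distinct(community$census, .data$plant_id, .data$time_point)
  bulk_grid <- tidyr::expand_grid(plants, compartment = bulk_comps,
                                  element = c("13C", "15N"))
  bulk <- bulk_grid |>
    dplyr::mutate(
      enr_mean = ifelse(
        .data$element == "13C",
        config$compartment_enr_13c[.data$compartment],
        config$compartment_enr_15n[.data$compartment]
      ),
      enr_true = pmax(0, stats::rnorm(
        dplyr::n(), .data$enr_mean, config$compartment_enr_rel_sd * .data$enr_mean
      )),
      conc = ifelse(
        .data$element == "13C",
        config$compartment_c_conc[.data$compartment],
        config$compartment_n_conc[.data$compartment]
      ),
      dry_mass_g = stats::runif(dplyr::n(), 5e-4, 1.5e-3),
      species = NA_character_
    )
  bulk_rows <- bulk |>
    dplyr::rowwise() |>
    dplyr::mutate(isotope_value = to_delta(.data$enr_true, .data$conc, .data$element)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      .data$plant_id, .data$time_point, .data$compartment, .data$species,
      .data$dry_mass_g, .data$element,
      element_mass_g = .data$conc / 1000 * .data$dry_mass_g,
      .data$isotope_value
    )

  # non-labelled controls at natural abundance, every compartment x element
  control_grid <- tidyr::expand_grid(
    plant_id = sprintf("C%02d", seq_len(config$n_controls)),
    compartment = c("BA", "CR", "FR", "LR", "EM", "RS"),
    element = c("13C", "15N")
  )
  control_rows <- control_grid |>
    dplyr::mutate(
      time_point = 0L,
      species = NA_character_,
      dry_mass_g = stats::runif(dplyr::n(), 5e-4, 1.5e-3),
      conc = ifelse(
        .data$element == "13C",
        config$compartment_c_conc[.data$compartment],
        config$compartment_n_conc[.data$compartment]
      ),
      element_mass_g = .data$conc / 1000 * .data$dry_mass_g,
      isotope_value = stats::rnorm(
        dplyr::n(),
        config$control_delta_mean[.data$element],
        config$control_delta_sd
      )
    ) |>
    dplyr::select(-"conc")

  measurements <- dplyr::bind_rows(
    dplyr::mutate(em_rows, is_control = FALSE),
    dplyr::mutate(bulk_rows, is_control = FALSE),
    dplyr::mutate(control_rows, is_control = TRUE)
  ) |>
    dplyr::mutate(value_kind = "delta_permil") |>
    dplyr::select(dplyr::all_of(measurement_columns))

  list(
    measurements = measurements,
    truth = list(
      em = em |> dplyr::select(
        "plant_id", "time_point", "species", "cn", "c_conc", "n_conc",
        "enr_13c_raw", "enr_13c", "enr_15n_raw", "enr_15n",
        "lr_13c", "lr_15n", "tip_biomass_g"
      ),
      bulk = bulk |> dplyr::select(
        "plant_id", "time_point", "compartment", "element", "enr_true"
      ),
      species = species_tbl,
      control_atom_fraction = af_control
    )
  )
}

#' Simulate a complete dual-isotope labeling study
#'
#' Orchestrates [generate_community()] and
#' [generate_isotope_measurements()] and adds the remaining input tables
#' (per-plant compartment biomasses, per-species tip biomass, cross-section
#' areas), together with a ground-truth record of every generating value, so
#' that any statistic the pipeline estimates can be scored against what
#' generated it.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; sub-stages use `seed`, `seed + 1`, `seed + 2`.
#' @return A `synthetic_study` list: `measurements`, `census`,
#'   `morphotypes`, `areas`, `tip_biomass`, `tip_totals`, `biomass`,
#'   `ground_truth`.
#' @examples
#' study <- simulate_study(simulation_config(n_plants = 4), seed = 1)
#' names(study)
#' @export
simulate_study <- function(config = simulation_config(), seed) {
  if (missing(seed)) stop_mycotrace("invalid_argument", "`seed` is mandatory.")
  community <- generate_community(config, seed = seed)
  meas <- generate_isotope_measurements(community, config, seed = seed + 1)

  set.seed(seed + 2)
  plants <- dplyr::distinct(community$census, .data$plant_id, .data$time_point)
  biomass <- plants |>
    dplyr::mutate(
      fine_root_g = pmax(0.5, stats::rnorm(dplyr::n(), config$fine_root_biomass_mean,
                                           config$fine_root_biomass_sd)),
      coarse_root_g = pmax(1, stats::rnorm(dplyr::n(), config$coarse_root_biomass_mean,
                                           config$coarse_root_biomass_sd)),
      soil_g = pmax(5, stats::rnorm(dplyr::n(), config$soil_mass_mean,
                                    config$soil_mass_sd))
    )
  areas <- meas$truth$species |>
    dplyr::filter(.data$dominant) |>
    dplyr::transmute(
      .data$species,
      area_total = stats::runif(dplyr::n(), 3e4, 8e4),
      fungal_pct = stats::runif(dplyr::n(), config$fungal_tissue_range[1],
                                config$fungal_tissue_range[2]),
      area_fungal = .data$fungal_pct / 100 * .data$area_total
    ) |>
    dplyr::select("species", "area_fungal", "area_total")

  structure(
    list(
      measurements = meas$measurements,
      census = community$census,
      morphotypes = community$morphotypes,
      areas = areas,
      tip_biomass = dplyr::select(meas$truth$species, "species", "tip_biomass_g"),
      tip_totals = community$tip_totals,
      biomass = biomass,
      ground_truth = list(
        config = config,
        seed = seed,
        species = meas$truth$species,
        em = meas$truth$em,
        bulk = meas$truth$bulk,
        control_atom_fraction = meas$truth$control_atom_fraction,
        abundance_expected = community$abundance_expected
      )
    ),
    class = "synthetic_study"
  )
}

#' Report the generating parameters of a synthetic study
#'
#' Flattens the scalar generating parameters into a two-column tibble
#' (attribute `"species"` carries the realized per-species values), the
#' record against which parameter-recovery scores are computed.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @return Tibble with columns `parameter`, `value`; attribute `species`.
#' @export
ground_truth_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  cfg <- study$ground_truth$config
  scalars <- cfg[vapply(cfg, function(x) is.numeric(x) && length(x) == 1, logical(1))]
  out <- tibble::tibble(
    parameter = c("seed", names(scalars)),
    value = c(study$ground_truth$seed, unlist(scalars, use.names = FALSE))
  )
  attr(out, "species") <- study$ground_truth$species
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic dual-isotope labeling study\n")
  cat(sprintf("  %d measurement rows (%d control), %d plants, %d species\n",
              nrow(x$measurements), sum(x$measurements$is_control),
              nrow(x$census), nrow(x$ground_truth$species)))
  cat(sprintf("  seed %d\n", x$ground_truth$seed))
  invisible(x)
}
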