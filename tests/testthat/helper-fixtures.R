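# Shared fixture builders. Everything is generated in code; no data files.

# a fast simulation configuration for tests that only need structure
small_config <- function(...) {
  simulation_config(
    n_plants = 4, n_controls = 4, census_tips = 200,
    ...
  )
}

# a noise-free configuration: every stochastic spread set to zero so the
# pipeline must invert the generator exactly
noiseless_config <- function(...) {
  simulation_config(
    n_plants = 4, n_controls = 4,
    noise_sd_13c = 0, noise_sd_15n = 0,
    lateral_noise_sd_13c = 0, lateral_noise_sd_15n = 0,
    cn_jitter_sd = 0, control_delta_sd = 0,
    compartment_enr_rel_sd = 0,
    ...
  )
}

# minimal hand-built measurement table in the delta dialect
tiny_measurements <- function() {
  tibble::tibble(
    plant_id = c("P1", "P1", "C1", "C2"),
    time_point = c(5L, 5L, 0L, 0L),
    compartment = "EM",
    species = c("sp1", "sp1", NA, NA),
    dry_mass_g = 0.001,
    element = "13C",
    element_mass_g = 0.0004,
    isotope_value = c(200, 150, -28, -28),
    value_kind = "delta_permil",
    is_control = c(FALSE, FALSE, TRUE, TRUE)
  )
}

# two-group community with tunable separation; disjoint = TRUE gives
# non-overlapping species supports
two_group_community <- function(n_per_group = 3, disjoint = TRUE, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  if (disjoint) {
    a <- cbind(matrix(runif(n_per_group * 3, 0.2, 0.5), n_per_group), 0, 0, 0)
    b <- cbind(0, 0, 0, matrix(runif(n_per_group * 3, 0.2, 0.5), n_per_group))
    comm <- rbind(a, b)
  } else {
    comm <- matrix(runif(n * 6, 0, 0.4), n)
  }
  list(comm = comm, groups = rep(c("g1", "g2"), each = n_per_group))
}
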