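test_that("identical seed and config give identical studies", {
  a <- simulate_study(small_config(), seed = 33)
  b <- simulate_study(small_config(), seed = 33)
  for (nm in c("measurements", "census", "morphotypes", "areas",
               "tip_biomass", "tip_totals", "biomass")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c <- simulate_study(small_config(), seed = 34)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("dominant taxa cover the configured share of tips", {
  cfg <- simulation_config(n_plants = 50, n_controls = 2)
  comm <- generate_community(cfg, seed = 2)
  ra <- relative_abundance(comm$morphotypes, comm$census)
  dominant <- comm$species$species[comm$species$dominant]
  per_plant <- ra |>
    dplyr::filter(species %in% dominant) |>
    dplyr::group_by(plant_id) |>
    dplyr::summarise(share = sum(rel_abundance))
  expect_lt(abs(mean(per_plant$share) - 0.8), 0.05)
})

test_that("a huge Dirichlet concentration equalizes abundances within class", {
  cfg <- simulation_config(n_plants = 2, n_controls = 2,
                           dirichlet_concentration = 1e7)
  comm <- generate_community(cfg, seed = 4)
  dominant <- comm$species$species[comm$species$dominant]
  ra <- relative_abundance(comm$morphotypes, comm$census) |>
    dplyr::filter(species %in% dominant)
  # every dominant species should sit near 0.8/7
  expect_true(all(abs(ra$rel_abundance - 0.8 / 7) < 0.05))
})

test_that("realized tip totals track the configured mean", {
  cfg <- simulation_config(n_plants = 50, n_controls = 2)
  comm <- generate_community(cfg, seed = 6)
  n <- nrow(comm$tip_totals)
  se <- cfg$total_tips_sd / sqrt(n)
  expect_lt(abs(mean(comm$tip_totals$total_em_tips) - cfg$total_tips_mean), 3 * se)
  # census rates are near their configured means
  rates <- census_rates(comm$census)
  expect_lt(abs(mean(rates$colonization_pct) - cfg$colonization_mean), 2)
  expect_lt(abs(mean(rates$vitality_pct) - cfg$vitality_mean), 2)
})

test_that("rectification keeps enrichments non-negative by default", {
  cfg <- small_config(intercept_13c = 0, slope_13c = 0,
                      intercept_15n = 0, slope_15n = 0,
                      control_delta_sd = 0)
  study <- simulate_study(cfg, seed = 11)
  enr <- compute_enrichment(study$measurements)
  em <- enr[enr$compartment == "EM", ]
  expect_true(all(em$enrichment_conc >= -1e-9))
  # ground truth still records the unrectified draws
  expect_true(any(study$ground_truth$em$enr_13c_raw < 0))
})

test_that("zero coupling noise with unit slope makes lateral roots mirror the symbiont", {
  cfg <- noiseless_config(lateral_coupling_slope_13c = 1,
                          lateral_coupling_slope_15n = 1)
  study <- simulate_study(cfg, seed = 12)
  truth <- study$ground_truth$em
  expect_equal(truth$lr_13c, truth$enr_13c, tolerance = 1e-12)
  expect_equal(truth$lr_15n, truth$enr_15n, tolerance = 1e-12)
})

test_that("generated deltas invert exactly through the enrichment chain", {
  study <- simulate_study(noiseless_config(), seed = 19)
  enr <- compute_enrichment(study$measurements)
  truth <- study$ground_truth$em
  em13 <- enr |>
    dplyr::filter(compartment == "EM", element == "13C") |>
    dplyr::inner_join(truth, by = c("plant_id", "time_point", "species"))
  expect_gt(nrow(em13), 10)
  expect_equal(em13$enrichment_conc, em13$enr_13c, tolerance = 1e-9)
  em15 <- enr |>
    dplyr::filter(compartment == "EM", element == "15N") |>
    dplyr::inner_join(truth, by = c("plant_id", "time_point", "species"))
  expect_equal(em15$enrichment_conc, em15$enr_15n, tolerance = 1e-9)
})

test_that("ground truth report echoes the scalar configuration", {
  cfg <- small_config()
  study <- simulate_study(cfg, seed = 9)
  rep <- ground_truth_report(study)
  expect_equal(rep$value[rep$parameter == "slope_13c"], cfg$slope_13c)
  expect_equal(rep$value[rep$parameter == "total_tips_mean"], cfg$total_tips_mean)
  expect_equal(rep$value[rep$parameter == "seed"], 9)
  sp <- attr(rep, "species")
  expect_true(all(sp$cn_species >= cfg$cn_range[1] & sp$cn_species <= cfg$cn_range[2]))
})
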