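test_that("delta to atom fraction matches direct evaluation and edge cases", {
  # R = 0.0111802 * 1 -> af = R/(1+R), evaluated independently
  expect_equal(delta_to_atom_fraction(0, "13C"),
               0.0111802 / 1.0111802, tolerance = 1e-12)
  expect_equal(round(delta_to_atom_fraction(0, "13C"), 7), 0.0110566)
  # the -1000 permil limit carries no heavy isotope at all
  expect_equal(delta_to_atom_fraction(-1000, "13C"), 0)
  expect_error(delta_to_atom_fraction(-1000.01, "15N"),
               class = "mycotrace_error_invalid_isotope_value")
  # strictly increasing in delta
  d <- seq(-900, 900, by = 100)
  expect_true(all(diff(delta_to_atom_fraction(d, "13C")) > 0))
})

test_that("delta <-> atom fraction round-trip is the identity", {
  for (sys in c("13C", "15N")) {
    for (d in c(-50, 0, 500, -999, 2500)) {
      back <- atom_fraction_to_delta(delta_to_atom_fraction(d, sys), sys)
      expect_equal(back, d, tolerance = 1e-12)
    }
  }
})

test_that("atom-percent excess is a scaled difference and antisymmetric", {
  expect_equal(atom_percent_excess(0.0110566, 0.0110566), 0)
  expect_equal(atom_percent_excess(0.02, 0.01), 1.0)
  # oracle: two independent delta conversions and subtraction
  af_lab <- delta_to_atom_fraction(200, "13C")
  af_con <- delta_to_atom_fraction(-28, "13C")
  expect_equal(atom_percent_excess(af_lab, af_con), (af_lab - af_con) * 100)
  # antisymmetry property across random fractions
  set.seed(11)
  a <- runif(50); b <- runif(50)
  expect_equal(atom_percent_excess(a, b), -atom_percent_excess(b, a))
  expect_error(atom_percent_excess(1.2, 0.5),
               class = "mycotrace_error_invalid_isotope_value")
})

test_that("enrichment concentration follows APE times element concentration", {
  expect_equal(enrichment_concentration(0, 0.4, 1), 0)
  expect_equal(enrichment_concentration(1, 0.4, 1), 4.0)
  # 0.5% APE of 419.7 mg/g carbon
  expect_equal(enrichment_concentration(0.5, 0.4197, 1), 2.0985)
  # linear in ape and element mass; bounded by the total element pool
  set.seed(4)
  ape <- runif(20, 0, 100); em <- runif(20, 0.1, 0.5)
  expect_equal(enrichment_concentration(2 * ape, em, 1),
               2 * enrichment_concentration(ape, em, 1))
  expect_true(all(enrichment_concentration(ape, em, 1) <= em * 1000 + 1e-9))
  expect_error(enrichment_concentration(1, 0.4, 0),
               class = "mycotrace_error_invalid_sample")
  expect_error(enrichment_concentration(1, 1.4, 1),
               class = "mycotrace_error_invalid_sample")
})

test_that("compartment amounts scale with biomass and sum over compartments", {
  expect_equal(compartment_amount(0, 5), 0)
  expect_equal(root_pool_amount(1.0, 3.9, 0.5, 12.5), 10.15)
  expect_equal(compartment_amount(2.5, 4), 2 * compartment_amount(2.5, 2))
  expect_error(compartment_amount(1, -1), class = "mycotrace_error_invalid_sample")
})

test_that("compute_enrichment reproduces hand-computed APE from deltas", {
  enr <- compute_enrichment(tiny_measurements())
  expect_equal(nrow(enr), 2)
  af_con <- delta_to_atom_fraction(-28, "13C")
  ape1 <- (delta_to_atom_fraction(200, "13C") - af_con) * 100
  expect_equal(enr$ape[1], ape1, tolerance = 1e-12)
  expect_equal(enr$element_conc_mg_g, c(400, 400))
  expect_equal(enr$enrichment_conc[1], ape1 / 100 * 400, tolerance = 1e-12)
  expect_false(any(enr$ape_negative))
})

test_that("compute_enrichment rejects mixed dialects and missing controls", {
  m <- tiny_measurements()
  m$value_kind[2] <- "atom_fraction"
  expect_error(compute_enrichment(m), class = "mycotrace_error_dialect")

  m2 <- tiny_measurements()
  m2$compartment[1:2] <- "FR"  # controls exist only for EM
  expect_error(compute_enrichment(m2),
               class = "mycotrace_error_missing_controls")

  m3 <- tiny_measurements()
  m3$dry_mass_g[1] <- -0.1
  expect_error(compute_enrichment(m3), class = "mycotrace_error_invalid_sample")
})

test_that("negative APE is retained and flagged, not clipped", {
  m <- tiny_measurements()
  m$isotope_value[1] <- -30  # below the control mean of -28
  enr <- compute_enrichment(m)
  expect_true(enr$ape[1] < 0)
  expect_true(enr$ape_negative[1])
})
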