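test_that("census rates match their defining ratios and scale invariance", {
  expect_equal(colonization_rate(90, 10), 90)
  expect_equal(colonization_rate(0, 50), 0)
  expect_equal(colonization_rate(372, 28), 372 * 100 / 400)
  expect_equal(vitality_rate(372, 28, 40), 400 * 100 / 440)
  expect_equal(vitality_rate(10, 5, 0), 100)
  expect_equal(vitality_rate(0, 0, 25), 0)
  # invariant to scaling all counts by a positive integer
  for (k in c(2L, 7L)) {
    expect_equal(colonization_rate(372 * k, 28 * k), colonization_rate(372, 28))
    expect_equal(vitality_rate(372 * k, 28 * k, 40 * k), vitality_rate(372, 28, 40))
  }
  expect_error(colonization_rate(0, 0), class = "mycotrace_error_undefined_rate")
  expect_error(vitality_rate(0, 0, 0), class = "mycotrace_error_undefined_rate")
})

test_that("relative abundance divides by vital mycorrhizal tips and keeps a remainder", {
  census <- tibble::tibble(plant_id = "P1", time_point = 5L,
                           n_vital_myco = 100L, n_vital_nonmyco = 10L, n_dry = 5L)
  morpho <- tibble::tibble(plant_id = "P1", time_point = 5L,
                           species = c("A", "B", "C"), n_tips = c(29L, 13L, 8L))
  ra <- relative_abundance(morpho, census)
  expect_equal(ra$rel_abundance[match(c("A", "B", "C"), ra$species)],
               c(0.29, 0.13, 0.08))
  expect_equal(ra$rel_abundance[ra$species == "unclassified"], 0.50)
  expect_equal(sum(ra$rel_abundance), 1)

  morpho_all <- tibble::tibble(plant_id = "P1", time_point = 5L,
                               species = "A", n_tips = 100L)
  ra2 <- relative_abundance(morpho_all, census)
  expect_equal(ra2$rel_abundance[ra2$species == "A"], 1.0)

  morpho_over <- dplyr::mutate(morpho, n_tips = c(80L, 30L, 8L))
  expect_error(relative_abundance(morpho_over, census),
               class = "mycotrace_error_inconsistent_census")
})

test_that("community matrix rows sum to at most one", {
  study <- simulate_study(small_config(), seed = 5)
  cm <- community_matrix(study$morphotypes, study$census)
  vals <- as.matrix(dplyr::select(cm, -plant_id, -time_point))
  expect_true(all(vals >= 0))
  expect_true(all(abs(rowSums(vals) - 1) < 1e-9))  # unclassified included
  cm2 <- community_matrix(study$morphotypes, study$census,
                          include_unclassified = FALSE)
  vals2 <- as.matrix(dplyr::select(cm2, -plant_id, -time_point))
  expect_true(all(rowSums(vals2) <= 1 + 1e-9))
})

test_that("fungal tissue fraction is a bounded percentage", {
  expect_equal(fungal_tissue_fraction(100, 100), 100)
  expect_equal(fungal_tissue_fraction(50, 100), 50)
  expect_equal(fungal_tissue_fraction(253, 1000), 25.3)
  expect_error(fungal_tissue_fraction(1001, 1000),
               class = "mycotrace_error_inconsistent_areas")
  expect_error(fungal_tissue_fraction(0, 0),
               class = "mycotrace_error_inconsistent_areas")
})

test_that("Bray-Curtis similarity: identity, symmetry, disjoint supports, hand value", {
  expect_equal(bray_curtis_similarity(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(bray_curtis_similarity(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  set.seed(2)
  for (i in 1:10) {
    a <- runif(6); b <- runif(6)
    expect_equal(bray_curtis_similarity(a, b), bray_curtis_similarity(b, a))
  }
  expect_error(bray_curtis_similarity(c(0, 0), c(0, 0)),
               class = "mycotrace_error_undefined_similarity")
})

test_that("Bray-Curtis dissimilarity matches vegan", {
  skip_if_not_installed("vegan")
  set.seed(9)
  m <- matrix(runif(8 * 5), nrow = 8)
  ours <- bray_curtis_dissimilarity(m)
  ref <- vegan::vegdist(m, method = "bray")
  expect_equal(as.vector(ours), as.vector(ref), tolerance = 1e-12)
})
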