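test_that("bead renderer matches analytic geometry and honours the seed", {
  # no capsule: bead only
  b0 <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 0,
                                       thickness_ratio = 0))
  expect_equal(sum(b0$image > 0.25 & b0$image <= 0.7), 0)
  expect_equal(sum(b0$image > 0.7), pi * 40^2, tolerance = 0.02)

  # full annulus, thickness ratio 1: annulus area 3*pi*R^2 within 2%
  b1 <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 360,
                                       thickness_ratio = 1, noise_sd = 0))
  expect_equal(sum(b1$image > 0.25 & b1$image <= 0.7), 3 * pi * 40^2,
               tolerance = 0.02)

  # rasterization fidelity holds down to radius 20
  b2 <- generate_bead_image(bead_truth(bead_radius = 20, coverage_deg = 360,
                                       thickness_ratio = 1, noise_sd = 0))
  expect_equal(sum(b2$image > 0.25 & b2$image <= 0.7), 3 * pi * 20^2,
               tolerance = 0.02)

  # determinism: same truth, same seed, byte-identical rasters
  t <- bead_truth(bead_radius = 30, coverage_deg = 120, thickness_ratio = 0.5,
                  noise_sd = 0.05, seed = 99)
  expect_identical(generate_bead_image(t)$image, generate_bead_image(t)$image)
  t2 <- bead_truth(bead_radius = 30, coverage_deg = 120, thickness_ratio = 0.5,
                   noise_sd = 0.05, seed = 100)
  expect_false(identical(generate_bead_image(t)$image,
                         generate_bead_image(t2)$image))
})

test_that("bead renderer rejects invalid geometry", {
  expect_error(bead_truth(coverage_deg = 400), "coverage_deg")
  expect_error(bead_truth(coverage_deg = -1), "coverage_deg")
  expect_error(bead_truth(thickness_ratio = -0.5), "thickness_ratio")
  expect_error(generate_bead_image(bead_truth(bead_radius = 40),
                                   image_size = c(60, 60)), "image_size")
  expect_error(generate_bead_image(bead_truth(bead_radius = 20),
                                   bead_center = c(10, 10)), "canvas")
})

test_that("bead cohorts follow the requested distributions", {
  # degenerate distributions: all truths identical
  coh <- generate_bead_cohort(10,
    coverage_dist = list(dist = "fixed", value = 360),
    thickness_dist = list(dist = "fixed", value = 1.5), seed = 1)
  expect_length(coh, 10)
  expect_true(all(vapply(coh, function(b) b$truth$coverage_deg, 1) == 360))
  expect_true(all(vapply(coh, function(b) b$truth$thickness_ratio, 1) == 1.5))

  # law of large numbers: uniform coverage mean near 180 within 3 SE
  draws <- withr::with_seed(7, {
    hemoquant:::.draw_dist(list(dist = "uniform", min = 0, max = 360), 1000)
  })
  se <- 360 / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(draws) - 180), 3 * se)

  expect_error(generate_bead_cohort(0, list(dist = "fixed", value = 1),
                                    list(dist = "fixed", value = 1)),
               "n_beads")
  expect_error(generate_bead_cohort(2, list(dist = "nope"),
                                    list(dist = "fixed", value = 1)),
               "distribution")
})

test_that("hemocyte fields carry exact ground truth and reproduce under seed", {
  ft <- field_truth(n_cells = 60, spread_fraction = 0, seed = 3)
  f <- generate_hemocyte_field(ft)
  expect_equal(nrow(f$records), 60)
  expect_false(any(f$records$spread))

  ft2 <- field_truth(n_cells = 80, spread_fraction = 0.6,
                     phagocytic_fraction = 0.5, mean_spots = 2, seed = 11)
  f2 <- generate_hemocyte_field(ft2)
  f2b <- generate_hemocyte_field(ft2)
  expect_identical(f2$dic_channel, f2b$dic_channel)
  expect_identical(f2$records, f2b$records)
  expect_true(all(f2$records$engulfed_count[f2$records$phagocytic] >= 1))
  expect_true(all(f2$records$engulfed_count[!f2$records$phagocytic] == 0))

  # binomial sampling bound on the realized spread fraction
  ft3 <- field_truth(n_cells = 500, spread_fraction = 0.6, seed = 21)
  f3 <- generate_hemocyte_field(ft3)
  expect_lt(abs(mean(f3$records$spread) - 0.6),
            3 * sqrt(0.6 * 0.4 / 500))

  # overcrowded field errors out rather than looping forever
  expect_error(generate_hemocyte_field(field_truth(n_cells = 50, seed = 1),
                                       image_size = c(100, 100)),
               "crowded")
})

test_that("fluorescence readings honour means, cv and replicate count", {
  r0 <- generate_factin_readings(c(a = 200, b = 150), cv = 0,
                                 n_per_group = 4, blank_mean = 100, seed = 1)
  expect_equal(nrow(r0), 12)  # 2 groups + blank, 4 rows each
  expect_equal(r0$intensity[r0$group == "a"], rep(200, 4))
  expect_equal(r0$intensity[r0$group == "blank"], rep(100, 4))

  # identity case: group mean equal to blank gives relative intensity 1
  rf <- relative_fluorescence(generate_factin_readings(
    c(x = 100), cv = 0, n_per_group = 4, blank_mean = 100, seed = 1))
  expect_equal(rf$per_group$mean_relative, 1.0)

  # lognormal generation recovers the requested mean
  big <- generate_factin_readings(c(a = 200), cv = 0.1, n_per_group = 4000,
                                  blank_mean = 100, seed = 5)
  expect_equal(mean(big$intensity[big$group == "a"]), 200, tolerance = 0.01)

  expect_error(generate_factin_readings(c(a = 100), cv = 1, n_per_group = 4,
                                        blank_mean = 10), "cv")
  expect_error(generate_factin_readings(c(a = -1), cv = 0, n_per_group = 4,
                                        blank_mean = 10), "positive")
})

test_that("docking tables respect ranges, seeds and degenerate cases", {
  tab <- generate_docking_table(c("a", "b"), n_conformers = 10,
                                energy_ranges = list(c(-9, -6), c(-8, -5)),
                                seed = 2)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$binding_energy_kcal_mol[tab$ligand == "a"] >= -9))
  expect_identical(tab, generate_docking_table(c("a", "b"), 10,
                   list(c(-9, -6), c(-8, -5)), seed = 2))

  deg <- generate_docking_table("palmitic", n_conformers = 10,
                                energy_ranges = list(c(-8.69, -8.69)),
                                seed = 1)
  expect_equal(attr(deg, "truth")$best_energy, -8.69)

  one <- generate_docking_table("x", n_conformers = 1,
                                energy_ranges = list(c(-7, -6)), seed = 3)
  expect_equal(select_best_pose(one)$binding_energy_kcal_mol,
               one$binding_energy_kcal_mol)

  expect_error(generate_docking_table(character(0), 10, list(c(-9, -6))),
               "nonempty")
  expect_error(generate_docking_table("a", 10, list(c(-6, -9))), "range")
})
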