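test_that("bead segmentation recovers centre and radius", {
  b <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 0,
                                      thickness_ratio = 0))
  bead <- segment_bead(b$image)
  side <- nrow(b$image)
  expect_lt(max(abs(bead$center - (side + 1) / 2)), 2)
  expect_equal(bead$radius_px, 40, tolerance = 0.03)

  # a full annulus must not inflate the fitted radius: the inner bead band
  # is segmented, not the capsule
  b2 <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 360,
                                       thickness_ratio = 1, noise_sd = 0.05,
                                       seed = 8))
  expect_equal(segment_bead(b2$image)$radius_px, 40, tolerance = 0.03)

  expect_error(segment_bead(matrix(0.05, 64, 64)), "no bead")
})

test_that("angular coverage is recovered to within 2 degrees", {
  for (cov in c(0, 90, 180, 333, 360)) {
    b <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = cov,
                                        thickness_ratio = 0.5,
                                        noise_sd = 0.05, seed = cov + 1))
    bead <- segment_bead(b$image)
    expect_lt(abs(measure_coverage_angle(b$image, bead) - cov), 2.5)
  }
})

test_that("total footprint area matches the analytic oracle within 2%", {
  cfg <- assay_config()
  b0 <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 0,
                                       thickness_ratio = 0))
  expect_equal(measure_total_area(b0$image, cfg), pi * 40^2, tolerance = 0.02)

  b1 <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 360,
                                       thickness_ratio = 1))
  expect_equal(measure_total_area(b1$image, cfg), 4 * pi * 40^2,
               tolerance = 0.02)

  b2 <- generate_bead_image(bead_truth(bead_radius = 40, coverage_deg = 90,
                                       thickness_ratio = 1))
  expect_equal(measure_total_area(b2$image, cfg),
               pi * 40^2 + (90 / 360) * 3 * pi * 40^2, tolerance = 0.02)

  # calibration scales areas quadratically
  cfg2 <- assay_config(pixel_size = 0.5)
  expect_equal(measure_total_area(b0$image, cfg2),
               measure_total_area(b0$image, cfg) / 4)
})

test_that("coverage fraction and thickness ratio follow their formulas", {
  expect_equal(area_fraction(0), 0)
  expect_equal(area_fraction(360), 1)
  expect_equal(area_fraction(120), 1 / 3)
  expect_error(area_fraction(361), "coverage_deg")

  expect_equal(thickness_ratio(pi * 40^2, 40), 0)
  expect_equal(thickness_ratio(4 * pi * 40^2, 40), 1)
  expect_equal(thickness_ratio(2.25 * pi * 40^2, 40), 0.5)
  # floored at zero when the footprint dips below the bead disk
  expect_equal(thickness_ratio(0.9 * pi * 40^2, 40), 0)
  expect_error(thickness_ratio(100, 0), "radius")
})

test_that("grade schemes bin A and T with exclusive-inclusive edges", {
  expect_identical(assign_grade(0, "area"), 0L)
  expect_identical(assign_grade(0, "thickness"), 0L)
  expect_identical(assign_grade(1 / 3, "area"), 2L)
  expect_identical(assign_grade(0.5, "thickness"), 3L)
  # shared endpoints go to the lower grade (upper-inclusive bins)
  expect_identical(assign_grade(c(0.25, 0.5, 0.75, 1), "area"),
                   c(1L, 2L, 3L, 4L))
  expect_identical(assign_grade(c(0.2, 0.4, 0.6, 0.8, 1.0, 2.0), "thickness"),
                   c(1L, 2L, 3L, 4L, 5L, 6L))
  # above the last printed thickness bin clamps to grade 6
  expect_identical(assign_grade(2.7, "thickness"), 6L)
  expect_error(assign_grade(1.2, "area"), "exceed")
  expect_error(assign_grade(-0.1, "thickness"), ">= 0")
})

test_that("encapsulation index equals the weighted-sum oracle and is bounded", {
  # hand-computed mixed cohort: half (4,6), half (2,2) gives 7.0
  mixed <- data.frame(area_grade = c(4, 4, 2, 2),
                      thickness_grade = c(6, 6, 2, 2))
  expect_equal(encapsulation_index(mixed)$encapsulation_index, 7.0)

  zero <- data.frame(area_grade = rep(0L, 5), thickness_grade = rep(0L, 5))
  expect_equal(encapsulation_index(zero)$encapsulation_index, 0)
  expect_equal(encapsulation_index(zero)$encapsulation_rate, 0)

  full <- data.frame(area_grade = rep(4L, 5), thickness_grade = rep(6L, 5))
  expect_equal(encapsulation_index(full)$encapsulation_index, 10)
  expect_equal(encapsulation_index(full)$encapsulation_rate, 1)

  # random grade tables: index in [0, 10], P sums to 1, and the weighted
  # sum equals mean(area) + mean(thickness) to 1e-12
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(3:30, 1)
      tab <- data.frame(area_grade = sample(0:4, n, TRUE),
                        thickness_grade = sample(0:6, n, TRUE))
      s <- encapsulation_index(tab)
      expect_gte(s$encapsulation_index, 0)
      expect_lte(s$encapsulation_index, 10)
      expect_equal(sum(s$P_area), 1, tolerance = 1e-9)
      expect_equal(sum(s$P_thickness), 1, tolerance = 1e-9)
      expect_equal(s$encapsulation_index,
                   mean(tab$area_grade) + mean(tab$thickness_grade),
                   tolerance = 1e-12)
    }
  })

  expect_error(encapsulation_index(data.frame()), "nonempty")
})

test_that("raising any single bead's grade never lowers the index", {
  withr::with_seed(1, {
    for (i in 1:50) {
      tab <- data.frame(area_grade = sample(0:4, 10, TRUE),
                        thickness_grade = sample(0:6, 10, TRUE))
      j <- sample(10, 1)
      bumped <- tab
      if (runif(1) < 0.5 && tab$area_grade[j] < 4)
        bumped$area_grade[j] <- tab$area_grade[j] + 1
      else if (tab$thickness_grade[j] < 6)
        bumped$thickness_grade[j] <- tab$thickness_grade[j] + 1
      expect_gte(encapsulation_index(bumped)$encapsulation_index,
                 encapsulation_index(tab)$encapsulation_index)
    }
  })
})

test_that("cohort pipeline flags unreadable images instead of aborting", {
  coh <- generate_bead_cohort(4,
    coverage_dist = list(dist = "uniform", min = 90, max = 360),
    thickness_dist = list(dist = "uniform", min = 0.2, max = 1),
    seed = 6, noise_sd = 0.05)
  imgs <- c(lapply(coh, `[[`, "image"), list(matrix(0.05, 64, 64)))
  res <- analyze_bead_cohort(imgs)
  expect_equal(sum(res$per_bead$ok), 4)
  expect_equal(sum(!res$per_bead$ok), 1)
  expect_match(res$per_bead$error[!res$per_bead$ok], "no bead")
  expect_equal(res$summary$n_beads, 4)
})

test_that("pipeline grades noiseless cohorts exactly as the ground truth", {
  coh <- generate_bead_cohort(10,
    coverage_dist = list(dist = "uniform", min = 0, max = 360),
    thickness_dist = list(dist = "uniform", min = 0.15, max = 1.2),
    seed = 19, noise_sd = 0)
  res <- analyze_bead_cohort(coh)
  truth <- do.call(rbind, lapply(coh, function(b)
    bead_truth_measurement(b$truth)))
  expect_equal(res$summary$encapsulation_index,
               encapsulation_index(truth)$encapsulation_index)
})
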