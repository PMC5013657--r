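# Evanescent-field height mapping: penetration depth, intensity inversion,
# footprint masks and outlines.

test_that("penetration depth matches direct evaluation and scales with wavelength", {
  opt <- optical_config()
  # independent re-derivation of the decay length for the 488-nm line
  oracle <- 488 / (4 * pi * sqrt((1.515 * sin(70 * pi / 180))^2 - 1.338^2))
  expect_equal(penetration_depth(opt, "mab24"), oracle, tolerance = 1e-12)
  expect_equal(penetration_depth(opt, 488), oracle, tolerance = 1e-12)
  expect_equal(oracle, 79.9, tolerance = 1e-3)
  # linear in wavelength
  expect_equal(penetration_depth(opt, "membrane") / penetration_depth(opt, "mab24"),
               641 / 488, tolerance = 1e-12)
  # larger angle -> shallower field
  opt75 <- optical_config(theta_deg = 75)
  expect_lt(penetration_depth(opt75, 488), penetration_depth(opt, 488))
})

test_that("configurations at or below the critical angle are rejected", {
  crit <- asin(1.338 / 1.515) * 180 / pi
  expect_error(optical_config(theta_deg = crit), "critical angle")
  expect_error(optical_config(theta_deg = crit - 5), "critical angle")
  expect_silent(optical_config(theta_deg = crit + 1))
})

test_that("intensity-to-height inversion honours the exponential decay law", {
  d <- 80
  i0 <- 2000
  bg <- 100
  frame <- matrix(bg + i0 * exp(-c(0, 80, 96.1, 250) / d), 1)
  hm <- intensity_to_height(frame, i0, d, bg)
  expect_equal(hm$delta[1, 1], 0)
  expect_equal(hm$delta[1, 2], 80, tolerance = 1e-9)
  expect_equal(hm$delta[1, 3], 96.1, tolerance = 1e-9)
  expect_false(hm$valid[1, 4])  # beyond the 200-nm validity range
  # worked value: 30% of I0 at d = 79.9 nm
  hm2 <- intensity_to_height(matrix(100 + 0.3 * 2000, 1), 2000, 79.9, 100)
  expect_equal(hm2$delta[1, 1], 79.9 * log(1 / 0.3), tolerance = 1e-12)
  expect_equal(hm2$delta[1, 1], 96.2, tolerance = 1e-3)
  # brighter than I0 clips to the interface, at/below background is invalid
  hm3 <- intensity_to_height(matrix(c(3 * i0, bg, bg - 5), 1), i0, d, bg)
  expect_equal(hm3$delta[1, 1], 0)
  expect_false(any(hm3$valid[1, 2:3]))
})

test_that("height is strictly decreasing in intensity", {
  i <- seq(280, 2000, length.out = 200)
  hm <- intensity_to_height(matrix(i, 1), i0 = 2000, d = 80, background = 100)
  expect_true(all(diff(hm$delta[1, ]) < 0))
})

test_that("reference-intensity estimation recovers a known I0", {
  # flat patch at the interface: brightest pixels carry I0 exactly
  frame <- matrix(100, 64, 64)
  disk <- (row(frame) - 32)^2 + (col(frame) - 32)^2 <= 20^2
  frame[disk] <- 100 + 2000
  est <- estimate_reference_intensity(frame)
  expect_equal(est$i0, 2000, tolerance = 0.01)
  expect_equal(est$background, 100, tolerance = 1e-6)
  # user-supplied I0 bypasses estimation
  est2 <- estimate_reference_intensity(frame, fixed_i0 = 1234)
  expect_identical(est2$i0, 1234)
  expect_identical(est2$method, "fixed")
  # frame indistinguishable from background
  expect_error(estimate_reference_intensity(matrix(100, 32, 32)),
               "above background")
})

test_that("footprint mask applies the 95-nm rule and keeps the main component", {
  delta <- matrix(c(50, 90, 100, 200), 1)
  hm <- height_map(delta, matrix(TRUE, 1, 4), i0 = 1, d = 80, background = 0)
  expect_equal(as.vector(footprint_mask(hm)), c(TRUE, TRUE, FALSE, FALSE))
  # satellites are dropped
  delta2 <- matrix(200, 9, 9)
  delta2[2:5, 2:5] <- 40
  delta2[8, 8] <- 40
  hm2 <- height_map(delta2, matrix(TRUE, 9, 9), 1, 80, 0)
  m <- footprint_mask(hm2)
  expect_equal(sum(m), 16)
  expect_false(m[8, 8])
  # min_px turns a tiny footprint into an empty mask
  expect_equal(sum(footprint_mask(hm2, min_px = 20)), 0)
  # all-invalid map
  hm3 <- height_map(matrix(NA_real_, 3, 3), matrix(FALSE, 3, 3), 1, 80, 0)
  expect_equal(sum(footprint_mask(hm3)), 0)
})

test_that("stricter height thresholds give nested footprints", {
  set.seed(11)
  for (rep in 1:5) {
    delta <- matrix(runif(400, 0, 220), 20, 20)
    hm <- height_map(delta, delta <= 200, 1, 80, 0)
    m50 <- footprint_mask(hm, 50, keep_largest = FALSE)
    m95 <- footprint_mask(hm, 95, keep_largest = FALSE)
    expect_true(all(m95[m50]))
  }
})

test_that("footprint outline is the one-pixel 4-connected boundary", {
  sq <- matrix(FALSE, 5, 5)
  sq[2:4, 2:4] <- TRUE
  expect_equal(sum(footprint_outline(sq)), 8)
  expect_equal(sum(footprint_outline(matrix(FALSE, 4, 4))), 0)
  # disk: agrees exactly with a brute-force boundary count and is close to
  # the true circumference
  m <- matrix(FALSE, 25, 25)
  m[(row(m) - 13)^2 + (col(m) - 13)^2 <= 100] <- TRUE
  out <- footprint_outline(m)
  brute <- 0L
  for (r in 1:25) {
    for (cc in 1:25) {
      if (!m[r, cc]) next
      nb <- c(
        if (r > 1) m[r - 1, cc] else FALSE,
        if (r < 25) m[r + 1, cc] else FALSE,
        if (cc > 1) m[r, cc - 1] else FALSE,
        if (cc < 25) m[r, cc + 1] else FALSE
      )
      if (!all(nb)) brute <- brute + 1L
    }
  }
  expect_equal(sum(out), brute)
  expect_lt(abs(sum(out) - 2 * pi * 10) / (2 * pi * 10), 0.15)
})

test_that("height recovery is exact on noise-free renders and consistent across wavelengths", {
  cfg <- scene_config(rng_seed = 4, poisson_noise = FALSE, read_noise_sd = 0)
  sc <- simulate_scene(cfg)
  mv <- render_movie(sc, noise = FALSE, channels = "membrane")
  f <- 31
  d <- penetration_depth(cfg$optics, "membrane")
  hm <- intensity_to_height(mv[, , 1, f], cfg$i0, d, cfg$background)
  gt <- scene_frame_truth(sc, f)
  inside <- !is.na(gt$delta)
  expect_lt(max(abs(hm$delta[inside] - gt$delta[inside])), 1e-9)
  # same scene imaged with a 561-nm membrane line gives the same heights
  opt561 <- optical_config(wavelengths_nm = c(mab24 = 488, kim127 = 641,
                                              membrane = 561))
  cfgB <- scene_config(rng_seed = 4, poisson_noise = FALSE,
                       read_noise_sd = 0, optics = opt561)
  mvB <- render_movie(simulate_scene(cfgB), noise = FALSE,
                      channels = "membrane")
  hmB <- intensity_to_height(mvB[, , 1, f], cfgB$i0,
                             penetration_depth(opt561, "membrane"),
                             cfgB$background)
  both <- hm$valid & hmB$valid
  expect_lt(max(abs(hm$delta[both] - hmB$delta[both])), 2)
})
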