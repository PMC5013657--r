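# Ground-truth scene generator: topography, motion, cluster placement,
# state evolution, rendering and cytometry fixtures.

test_that("topography hits the target hill fraction and is reproducible", {
  cfg <- scene_config(rng_seed = 21)
  topo <- build_topography(cfg)
  expect_gte(topo$hill_fraction, 0.24)
  expect_lte(topo$hill_fraction, 0.30)
  expect_true(all(topo$delta[topo$disk] >= 0))
  expect_true(all(topo$delta[topo$disk] <= cfg$microvillus_height_nm))
  expect_identical(build_topography(cfg)$delta, topo$delta)
  # hills sit lower (closer to the interface) than valleys
  expect_lt(mean(topo$delta[topo$hill]),
            mean(topo$delta[topo$disk & !topo$hill]))
})

test_that("zero hill fraction gives a flat field with no hills", {
  cfg <- scene_config(hill_fraction = 0, rng_seed = 1)
  topo <- build_topography(cfg)
  expect_equal(sum(topo$hill), 0)
  expect_equal(var(topo$delta[topo$disk]), 0)
})

test_that("scene configuration validates its invariants", {
  expect_error(scene_config(image_shape = c(0, 64)), "positive")
  expect_error(scene_config(hill_fraction = 1), "hill_fraction")
  expect_error(scene_config(frame_interval_s = 0.5), "frame_interval")
  expect_error(scene_config(rolling_velocity_um_s = -1), ">= 0")
  expect_error(scene_config(arrest_time_s = 100), "arrest_time")
  expect_error(scene_config(cluster_counts = c("bogus" = 3)), "classes")
})

test_that("cell track rolls then arrests with the configured kinematics", {
  cfg <- scene_config(jitter_sd_um = 0, rng_seed = 1)
  tr <- build_cell_track(cfg)
  pre <- tr$time_s <= 0
  # 30 s of rolling at 1 um/s covers 30 um
  expect_equal(tr$x_um[tr$time_s == 0] - tr$x_um[1], 30, tolerance = 1e-9)
  expect_true(all(abs(diff(tr$x_um[pre]) - 1) < 1e-9))
  post <- tr$time_s >= 0
  expect_equal(var(tr$x_um[post]), 0)
  # zero velocity: stationary from the first frame
  tr0 <- build_cell_track(scene_config(rolling_velocity_um_s = 0,
                                       jitter_sd_um = 0, rng_seed = 1))
  expect_equal(var(tr0$x_um), 0)
})

test_that("centroid jitter keeps pre-arrest frame speeds near the rolling velocity", {
  cfg <- scene_config(jitter_sd_um = 0.05, rng_seed = 3)
  tr <- build_cell_track(cfg)
  sp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / cfg$frame_interval_s
  pre <- which(tr$time_s < -1)
  expect_true(all(sp[pre] > 0.8 & sp[pre] < 1.2))
})

test_that("cluster placement respects counts, disjointness and seeding bias", {
  cfg <- scene_config(rng_seed = 7)
  topo <- build_topography(cfg)
  cl <- init_clusters(cfg, topo)
  expect_equal(nrow(cl$table), 21)
  expect_equal(as.integer(table(cl$table$class)[c("E+H-", "E-H+", "E+H+")]),
               c(9L, 9L, 3L))
  all_px <- unlist(cl$pixels)
  expect_equal(length(all_px), length(unique(all_px)))  # disjoint
  expect_true(all(topo$disk[all_px]))                   # inside the footprint
  expect_true(all(cl$table$area_px == cfg$cluster_area_px))
  # forced hill seeding
  cfg_h <- scene_config(hill_bias = c("E+H+" = 1, "E+H-" = 1, "E-H+" = 1),
                        rng_seed = 8)
  cl_h <- init_clusters(cfg_h, build_topography(cfg_h))
  expect_true(all(cl_h$table$seed_on_hill))
})

test_that("hill-seeded fraction of a large cohort follows the configured bias", {
  cfg <- scene_config(image_shape = c(240, 240), cell_radius_um = 7,
                      cluster_counts = c("E+H+" = 200), rng_seed = 11)
  cl <- init_clusters(cfg, build_topography(cfg))
  frac <- mean(cl$table$seed_on_hill)
  ci <- 0.70 + c(-1.96, 1.96) * sqrt(0.70 * 0.30 / 200)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("state evolution obeys the allowed transition graph", {
  allowed <- c("E-H-:E+H-", "E-H-:E-H+", "E+H-:E+H+", "E-H+:E+H+")
  for (seed in 1:3) {
    ev <- evolve_states(rep(state_classes(), 30),
                        state_model_params(p_bent_to_ext = 0.2,
                                           p_bent_to_high = 0.2,
                                           p_ext_to_full = 0.3,
                                           p_high_to_full = 0.3),
                        n_steps = 12, seed = seed)
    if (nrow(ev$events)) {
      expect_true(all(paste(ev$events$from, ev$events$to, sep = ":") %in%
                        allowed))
    }
    # no reverse moves: per-cluster class codes never decrease in activation
    rank <- c("E-H-" = 0, "E+H-" = 1, "E-H+" = 1, "E+H+" = 2)
    expect_true(all(apply(ev$classes, 1, function(cl) {
      all(diff(rank[cl]) >= 0)
    })))
  }
  # zero rates freeze the classes
  ev0 <- evolve_states(c("E+H-", "E-H+"),
                       state_model_params(0, 0, 0, 0), 10, seed = 1)
  expect_equal(nrow(ev0$events), 0)
  expect_true(all(ev0$classes[1, ] == "E+H-"))
  expect_error(state_model_params(p_ext_to_full = 1.4), "0, 1")
})

test_that("the default extension rate converts one third of clusters in 4 s", {
  n <- 800
  ev <- evolve_states(rep("E+H-", n), state_model_params(), n_steps = 5,
                      seed = 42)
  frac <- mean(ev$classes[, 5] == "E+H+")
  ci <- 1 / 3 + c(-1.96, 1.96) * sqrt((1 / 3) * (2 / 3) / n)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("cis blocking shortens the bent-open lifetime as configured", {
  ev_ctl <- evolve_states(rep("E-H+", 500), state_model_params(), 41,
                          seed = 21)
  ev_blk <- evolve_states(rep("E-H+", 500),
                          state_model_params(cis_block = TRUE), 41,
                          seed = 22)
  d_ctl <- cluster_duration(ev_ctl$classes, 0:40)
  d_blk <- cluster_duration(ev_blk$classes, 0:40)
  expect_gt(mean(d_ctl, na.rm = TRUE), 5)
  expect_lt(mean(d_blk, na.rm = TRUE), 2)
})

test_that("per-frame visible cluster counts are conserved in the truth table", {
  sc <- simulate_scene(scene_config(rng_seed = 2))
  visible <- sc$states$classes != "E-H-"
  per_frame <- table(factor(sc$cluster_table$frame,
                            levels = seq_len(sc$config$n_frames)))
  expect_equal(as.integer(per_frame), colSums(visible))
})

test_that("rendering follows the evanescent excitation physics", {
  cfg <- scene_config(rng_seed = 4, poisson_noise = FALSE, read_noise_sd = 0)
  sc <- simulate_scene(cfg)
  mv <- render_movie(sc, noise = FALSE)
  f <- 31
  gt <- scene_frame_truth(sc, f)
  d_mem <- penetration_depth(cfg$optics, "membrane")
  inside <- !is.na(gt$delta)
  expected <- cfg$background + cfg$i0 * exp(-gt$delta[inside] / d_mem)
  expect_equal(mv[, , "membrane", f][inside], expected, tolerance = 1e-12)
  # outside the contact zone only background
  expect_true(all(mv[, , "membrane", f][!inside] == cfg$background))
  # a membrane patch at the interface returns background + I0
  cfg_flat <- scene_config(hill_fraction = 0, hill_delta_nm = -1,
                           valley_delta_nm = 1e-9, rng_seed = 4,
                           poisson_noise = FALSE, read_noise_sd = 0)
  mv_flat <- render_movie(simulate_scene(cfg_flat), noise = FALSE,
                          channels = "membrane")
  fp <- !is.na(scene_frame_truth(simulate_scene(cfg_flat), f)$delta)
  expect_equal(max(mv_flat[, , 1, f]), cfg_flat$background + cfg_flat$i0,
               tolerance = 1e-6)
  expect_true(all(abs(mv_flat[, , 1, f][fp] -
                        (cfg_flat$background + cfg_flat$i0)) < 1e-6))
})

test_that("noise preserves the mean image and rendering is seed-deterministic", {
  cfg <- scene_config(rng_seed = 4)
  sc <- simulate_scene(cfg)
  clean <- render_movie(sc, noise = FALSE)
  noisy <- render_movie(sc)
  expect_lt(abs(mean(noisy) - mean(clean)) / mean(clean), 0.02)
  expect_identical(noisy, render_movie(sc))
})

test_that("bead panels follow the linear response and recover the slope", {
  p <- make_bead_panel()
  expect_equal(p$mfi, c(5, 105, 405, 1005, 2005))
  expect_error(make_bead_panel(abc_levels = c(5e4, 5e4)), "distinct")
  pn <- make_bead_panel(noise_sd = 10, n_rep = 3, seed = 5)
  fit <- fit_bead_calibration(pn)
  expect_lt(abs(fit$slope - 0.02), 3 * fit$slope_se)
})

test_that("FRET series quench to the configured plateau", {
  s <- make_fret_series(true_e = 0.3, f_d = 1000, tau_s = 5)
  expect_equal(min(s$donor), 700, tolerance = 1e-3)
  expect_equal(s$donor[s$time_s < 10], rep(1000, 10))
  flat <- make_fret_series(true_e = 0)
  expect_equal(var(flat$donor), 0)
  # round trip with noise
  sn <- make_fret_series(true_e = 0.3, noise_sd = 5, seed = 3)
  qg <- quench_gain_stats(sn, attr(sn, "addition_time_s"))
  expect_lt(abs(qg$efficiency - 0.3), 0.02)
})

test_that("aggregation fixtures contain the requested double positives", {
  ev <- make_aggregation_events(45, 45, 10, seed = 1)
  expect_equal(nrow(ev), 100)
  expect_equal(heteroaggregate_fraction(ev), 10)
  ev0 <- make_aggregation_events(0, 0, 0, seed = 1)
  expect_equal(nrow(ev0), 0)
  expect_error(heteroaggregate_fraction(ev0), "undefined")
  big <- make_aggregation_events(1000, 1000, 250, seed = 2)
  expect_equal(heteroaggregate_fraction(big), 100 * 250 / 2250,
               tolerance = 1e-9)
})
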