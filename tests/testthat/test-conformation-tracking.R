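# Conformation classification, cell tracking/arrest, cluster linking and
# transition history.

test_that("pixel classification follows the two-reporter truth table", {
  k <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  cm <- classify_pixels(k, m)
  expect_equal(as.vector(unclass(cm)), c(3L, 1L, 2L, 0L))
  expect_equal(attr(cm, "classes"), c("E+H-", "E-H+", "E+H+"))
})

test_that("classes partition the reporter union and swap under dye switch", {
  set.seed(6)
  for (rep in 1:5) {
    k <- matrix(runif(400) < 0.3, 20, 20)
    m <- matrix(runif(400) < 0.3, 20, 20)
    cm <- unclass(classify_pixels(k, m))
    expect_equal(sum(cm == 1L) + sum(cm == 2L) + sum(cm == 3L), sum(k | m))
    sw <- unclass(classify_pixels(m, k))
    expect_equal(sw == 1L, cm == 2L)
    expect_equal(sw == 2L, cm == 1L)
    expect_equal(sw == 3L, cm == 3L)
  }
})

test_that("mixed components are counted once under the majority rule", {
  k <- matrix(FALSE, 6, 6)
  m <- matrix(FALSE, 6, 6)
  k[2:3, 1:5] <- TRUE          # 10-px component, all extension-positive
  m[2:3, 1:3] <- TRUE          # 6 of them also headpiece-positive
  s <- summarize_classes(classify_pixels(k, m))
  expect_equal(s$n_clusters[s$class == "E+H+"], 1)
  expect_equal(sum(s$n_clusters), 1)
  expect_equal(s$total_area_px[s$class == "E+H+"], 10)
  # empty maps
  s0 <- summarize_classes(classify_pixels(matrix(FALSE, 4, 4),
                                          matrix(FALSE, 4, 4)))
  expect_true(all(s0$n_clusters == 0))
})

test_that("configured class counts are recovered from a noise-free render", {
  cfg <- scene_config(arrest_time_s = 0, duration_s = 4,
                      poisson_noise = FALSE, read_noise_sd = 0,
                      rng_seed = 2)
  sc <- simulate_scene(cfg)
  mv <- render_movie(sc, noise = FALSE)
  a <- analyse_frame(mv, 1, cfg$optics, fixed_i0 = cfg$i0,
                     background = cfg$background)
  s <- summarize_classes(a$conf)
  expect_equal(s$n_clusters[match(c("E+H-", "E-H+", "E+H+"), s$class)],
               unname(truth_counts(sc, 1)))
})

test_that("cell tracking measures translation velocity from footprints", {
  mk <- function(col0) {
    m <- matrix(FALSE, 20, 60)
    m[8:12, col0:(col0 + 4)] <- TRUE
    m
  }
  # 1 px/frame at 1000-nm pixels = 1 um/s at 1 fps
  masks <- lapply(c(1, 2, 3, 4, 5), mk)
  tr <- track_cell(masks, frame_interval_s = 1, pixel_size_nm = 1000)
  expect_equal(tr$velocity_um_s[1:4], rep(1, 4), tolerance = 1e-9)
  expect_equal(tr$displacement_um[5], 4, tolerance = 1e-9)
  static <- track_cell(rep(list(mk(10)), 4), 1, 1000)
  expect_equal(static$velocity_um_s[1:3], rep(0, 3))
  # empty frames carry NA coordinates
  tr2 <- track_cell(c(list(matrix(FALSE, 20, 60)), masks), 1, 1000)
  expect_true(is.na(tr2$x_um[1]))
})

test_that("arrest detection applies the threshold with a confirmation window", {
  trk <- data.frame(time_s = 0:5,
                    velocity_um_s = c(1.0, 0.8, 0.4, 0.05, 0.02, 0.03))
  expect_equal(detect_arrest(trk), 3)
  none <- data.frame(time_s = 0:5, velocity_um_s = rep(0.5, 6))
  expect_true(is.na(detect_arrest(none)))
  # a one-frame dip does not count as arrest
  dip <- data.frame(time_s = 0:5,
                    velocity_um_s = c(1.0, 0.05, 0.5, 0.5, 0.5, 0.5))
  expect_true(is.na(detect_arrest(dip)))
  # a below-threshold run truncated by the end of the track still counts
  tail_run <- data.frame(time_s = 0:4,
                         velocity_um_s = c(1, 1, 1, 0.05, 0.02))
  expect_equal(detect_arrest(tail_run), 3)
})

test_that("arrest on ground-truth footprints matches the configured time", {
  for (i in 1:3) {
    v <- c(0.6, 1.4, 2.8)[i]
    cfg <- rolling_scene_config(v, seed = 300 + i)
    sc <- simulate_scene(cfg)
    fps <- lapply(seq_len(cfg$n_frames), function(f) {
      scene_frame_truth(sc, f)$footprint
    })
    tr <- track_cell(fps, cfg$frame_interval_s, cfg$pixel_size_nm,
                     times_s = sc$cell_track$time_s)
    a <- detect_arrest(tr)
    expect_lte(abs(a - 0), cfg$frame_interval_s)
  }
})

test_that("static clusters are linked into full-length tracks", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L
  lab[7:8, 7:8] <- 2L
  links <- link_clusters(rep(list(lab), 10))
  expect_equal(length(unique(links$track_id)), 2)
  expect_true(all(table(links$track_id) == 10))
  # disappearance terminates the track
  lab2 <- lab
  lab2[2:3, 2:3] <- 0L
  links2 <- link_clusters(c(rep(list(lab), 5), rep(list(lab2), 5)))
  lens <- table(links2$track_id)
  expect_equal(sort(as.integer(lens)), c(5, 10))
})

test_that("linking compensates rigid cell motion via offsets", {
  base <- matrix(0L, 20, 40)
  base[5:7, 3:5] <- 1L
  shift_map <- function(dx) {
    m <- matrix(0L, 20, 40)
    m[5:7, (3 + dx):(5 + dx)] <- 1L
    m
  }
  maps <- lapply(c(0, 8, 16, 24), shift_map)
  offsets <- cbind(row = rep(0, 4), col = c(0, 8, 16, 24))
  links <- link_clusters(maps, offsets_px = offsets)
  expect_equal(length(unique(links$track_id)), 1)
  # without compensation the displaced cluster starts new tracks
  links_nc <- link_clusters(maps)
  expect_equal(length(unique(links_nc$track_id)), 4)
})

test_that("transition history dates the first fully activated pixel", {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 1L
  kim_on <- lab > 0L
  mab_off <- matrix(FALSE, 6, 6)
  conf <- list(classify_pixels(kim_on, mab_off),
               classify_pixels(kim_on, mab_off),
               classify_pixels(kim_on, kim_on))
  h <- transition_history(link_clusters(rep(list(lab), 3)),
                          rep(list(lab), 3), conf, times_s = 0:2)
  expect_equal(h$tracks$initial_class, "E+H-")
  expect_equal(h$tracks$duration_s, 2)
  expect_equal(h$summary$fraction_within[h$summary$initial_class == "E+H-"], 1)
  # never transitions
  conf0 <- rep(list(classify_pixels(kim_on, mab_off)), 3)
  h0 <- transition_history(link_clusters(rep(list(lab), 3)),
                           rep(list(lab), 3), conf0, times_s = 0:2)
  expect_true(is.na(h0$tracks$duration_s))
  expect_equal(h0$summary$fraction_within[h0$summary$initial_class == "E+H-"], 0)
})

test_that("cluster durations run from first observation to first E+H+", {
  times <- 0:10
  cl <- rep(NA_character_, 11)
  cl[4:11] <- "E-H+"
  cl[9:11] <- "E+H+"
  expect_equal(cluster_duration(cl, times), 5)  # appears at 3 s, yellow at 8 s
  expect_equal(cluster_duration(rep("E+H+", 5), 0:4), 0)
  expect_true(is.na(cluster_duration(rep("E-H+", 5), 0:4)))
  m <- rbind(cl, rep("E+H+", 11))
  expect_equal(unname(cluster_duration(m, times)), c(5, 0))
})
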