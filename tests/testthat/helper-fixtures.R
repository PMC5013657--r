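# Shared fixture builders for the test suite.  Everything is generated in
# code; no stored image data.

# Analyse one rendered frame: reference intensity, height map, footprint,
# reporter labels and conformation map.  `fixed_i0`/`background` may pin
# the calibration to the ground truth for exact-inversion tests.
analyse_frame <- function(movie, frame, optics, fixed_i0 = NULL,
                          background = NULL,
                          segp = segmentation_params(), min_px = 50) {
  d <- penetration_depth(optics, "membrane")
  mem <- movie[, , "membrane", frame]
  est <- estimate_reference_intensity(mem, background = background,
                                      fixed_i0 = fixed_i0)
  hm <- intensity_to_height(mem, i0 = est$i0, d = d,
                            background = est$background)
  fp <- footprint_mask(hm, min_px = min_px)
  kim <- segment_clusters(movie[, , "kim127", frame], fp, segp)
  mab <- segment_clusters(movie[, , "mab24", frame], fp, segp)
  list(est = est, hm = hm, fp = fp, kim = kim, mab = mab,
       conf = classify_pixels(kim > 0L, mab > 0L))
}

# Ground-truth per-class cluster counts of a scene at a frame.
truth_counts <- function(scene, frame) {
  cls <- scene$states$classes[, frame]
  vapply(conformation_classes(), function(cl) sum(cls == cl), integer(1))
}

# A lattice of identically shaped 2x2 clusters whose classes follow an
# evolve_states() run: returns per-frame label maps and conformation maps.
# Lets tracking statistics run on hundreds of clusters without rendering.
grid_cohort <- function(n_side, initial_class, params, n_steps, seed,
                        spacing = 7L) {
  ev <- evolve_states(rep(initial_class, n_side^2), params, n_steps,
                      seed = seed)
  sz <- n_side * spacing + 3L
  base <- matrix(0L, sz, sz)
  id <- 0L
  coords <- vector("list", n_side^2)
  for (i in seq_len(n_side)) {
    for (j in seq_len(n_side)) {
      id <- id + 1L
      r <- (i - 1L) * spacing + 2L
      cc <- (j - 1L) * spacing + 2L
      base[r:(r + 1L), cc:(cc + 1L)] <- id
      coords[[id]] <- c(r, cc)
    }
  }
  frames <- lapply(seq_len(n_steps), function(f) {
    kim <- matrix(FALSE, sz, sz)
    mab <- matrix(FALSE, sz, sz)
    for (k in seq_len(id)) {
      cl <- ev$classes[k, f]
      rc <- coords[[k]]
      if (cl %in% c("E+H-", "E+H+")) {
        kim[rc[1]:(rc[1] + 1L), rc[2]:(rc[2] + 1L)] <- TRUE
      }
      if (cl %in% c("E-H+", "E+H+")) {
        mab[rc[1]:(rc[1] + 1L), rc[2]:(rc[2] + 1L)] <- TRUE
      }
    }
    list(labels = base, conf = classify_pixels(kim, mab))
  })
  list(evolution = ev,
       labels = lapply(frames, `[[`, "labels"),
       conf = lapply(frames, `[[`, "conf"))
}

# Wide-field rolling scene for arrest-detection checks.
rolling_scene_config <- function(velocity_um_s, seed) {
  scene_config(image_shape = c(80, 352), duration_s = 14, arrest_time_s = 6,
               rolling_velocity_um_s = velocity_um_s, rng_seed = seed)
}

# Footprint masks of a rendered membrane movie, frame by frame.
movie_footprints <- function(movie, optics, threshold_nm = 95, min_px = 50) {
  d <- penetration_depth(optics, "membrane")
  lapply(seq_len(dim(movie)[4]), function(f) {
    est <- tryCatch(estimate_reference_intensity(movie[, , "membrane", f]),
                    error = function(e) NULL)
    if (is.null(est)) {
      return(matrix(FALSE, dim(movie)[1], dim(movie)[2]))
    }
    hm <- intensity_to_height(movie[, , "membrane", f], est$i0, d,
                              est$background)
    footprint_mask(hm, threshold_nm = threshold_nm, min_px = min_px)
  })
}
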