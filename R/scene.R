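# Synthetic ground-truth scenes for the TqDF analysis pipeline.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a membrane draped over microvilli (bimodal height field inside a
# roughly circular contact zone), reporter-antibody clusters of ~25 px with
# class-dependent hill/valley placement, rolling-then-arrest motion, and
# discrete-time two-pathway conformational transitions.

#' Conformation class labels
#'
#' The three reporter-visible integrin conformations: `E+H-` (extended,
#' closed headpiece; extension reporter only), `E-H+` (bent, open
#' headpiece; headpiece reporter only) and `E+H+` (extended-open; both
#' reporters).  The latent `E-H-` (bent-closed) state binds neither
#' reporter and is invisible to imaging.
#'
#' @return character vector of the three visible class labels.
#' @export
conformation_classes <- function() c("E+H-", "E-H+", "E+H+")

state_classes <- function() c("E-H-", conformation_classes())

#' Synthetic scene configuration
#'
#' Defaults describe a neutrophil rolling into the field of view at
#' ~1 um/s, arresting at the image centre, with ~27% of the footprint on
#' membrane hills (microvillus tips), and 9/9/3 reporter clusters of
#' ~25 px (~0.1 um^2) in the `E+H-`/`E-H+`/`E+H+` classes at scene start.
#' Extended and extended-open clusters seed preferentially on hills
#' (biases 0.68 and 0.70); bent-open clusters seed mostly in valleys
#' (bias 0.29).
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size_nm pixel size, nm (default 64).
#' @param frame_interval_s acquisition interval, s (default 1, valid 1-5).
#' @param duration_s movie length, s.
#' @param arrest_time_s time of arrest measured from movie start, s.
#'   Reported times are relative to arrest (negative while rolling).
#' @param rolling_velocity_um_s pre-arrest rolling velocity, um/s.
#' @param jitter_sd_um per-frame centroid jitter SD while rolling, um;
#'   reduced tenfold after arrest.
#' @param hill_fraction target area fraction of hills in the footprint.
#' @param microvillus_height_nm microvillus height scale, nm; caps the
#'   height field.
#' @param hill_delta_nm membrane height over microvillus tips, nm.
#' @param valley_delta_nm membrane height between microvilli, nm (must stay
#'   below the 95-nm footprint cutoff so the contact disk is one footprint).
#' @param cell_radius_um footprint radius, um.
#' @param cluster_counts named integer vector of initial cluster counts per
#'   class; may include latent `E-H-` clusters that only become visible
#'   after a transition.
#' @param cluster_area_px target cluster size in pixels (default 25).
#' @param cluster_buffer_px minimum pixel gap kept between clusters.
#' @param hill_bias named per-class probability that a cluster seeds on a
#'   hill.
#' @param background counts added everywhere.
#' @param i0 membrane-channel reference intensity above background at
#'   height 0, counts.
#' @param reporter_amplitude reporter-channel cluster amplitude above
#'   background at height 0, counts.
#' @param photon_scale counts per photon for the Poisson noise model.
#' @param read_noise_sd additive Gaussian read noise SD, counts.
#' @param poisson_noise logical, apply shot noise when rendering.
#' @param psf_sigma_px Gaussian PSF SD applied to reporter channels, px.
#' @param optics an [optical_config()]; pixel size is taken from this
#'   configuration's `pixel_size_nm` argument.
#' @param rng_seed integer seed; all generator stages are deterministic
#'   given the configuration and this seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(64, 64),
                         pixel_size_nm = 64,
                         frame_interval_s = 1,
                         duration_s = 60,
                         arrest_time_s = 30,
                         rolling_velocity_um_s = 1.0,
                         jitter_sd_um = 0.02,
                         hill_fraction = 0.27,
                         microvillus_height_nm = 200,
                         hill_delta_nm = 5,
                         valley_delta_nm = 82,
                         cell_radius_um = 2.0,
                         cluster_counts = c("E+H-" = 9, "E-H+" = 9,
                                            "E+H+" = 3, "E-H-" = 0),
                         cluster_area_px = 25,
                         cluster_buffer_px = 3,
                         hill_bias = c("E+H+" = 0.70, "E+H-" = 0.68,
                                       "E-H+" = 0.29, "E-H-" = 0.29),
                         background = 100,
                         i0 = 2000,
                         reporter_amplitude = 1500,
                         photon_scale = 1,
                         read_noise_sd = 3,
                         poisson_noise = TRUE,
                         psf_sigma_px = 0.6,
                         optics = NULL,
                         rng_seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape <= 0)) {
    stop_config("image_shape must be two positive pixel counts")
  }
  if (frame_interval_s < 1 || frame_interval_s > 5) {
    stop_config("frame_interval_s must lie in [1, 5] s")
  }
  if (hill_fraction < 0 || hill_fraction >= 1) {
    stop_config("hill_fraction must lie in [0, 1)")
  }
  if (rolling_velocity_um_s < 0) stop_config("rolling_velocity_um_s must be >= 0")
  if (cluster_area_px < 1) stop_config("cluster_area_px must be >= 1 px")
  if (any(cluster_counts < 0)) stop_config("cluster counts must be >= 0")
  if (!all(names(cluster_counts) %in% state_classes())) {
    stop_config("cluster_counts names must be conformation classes")
  }
  if (arrest_time_s < 0 || arrest_time_s > duration_s) {
    stop_config("arrest_time_s must lie within [0, duration_s]")
  }
  if (valley_delta_nm <= hill_delta_nm) {
    stop_config("valley_delta_nm must exceed hill_delta_nm")
  }
  if (is.null(optics)) optics <- optical_config(pixel_size_nm = pixel_size_nm)
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s,
    duration_s = duration_s,
    arrest_time_s = arrest_time_s,
    rolling_velocity_um_s = rolling_velocity_um_s,
    jitter_sd_um = jitter_sd_um,
    hill_fraction = hill_fraction,
    microvillus_height_nm = microvillus_height_nm,
    hill_delta_nm = hill_delta_nm,
    valley_delta_nm = valley_delta_nm,
    cell_radius_um = cell_radius_um,
    cluster_counts = cluster_counts,
    cluster_area_px = cluster_area_px,
    cluster_buffer_px = cluster_buffer_px,
    hill_bias = hill_bias,
    background = background,
    i0 = i0,
    reporter_amplitude = reporter_amplitude,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    poisson_noise = poisson_noise,
    psf_sigma_px = psf_sigma_px,
    optics = optics,
    rng_seed = as.integer(rng_seed)
  )
  cfg$n_frames <- as.integer(round(duration_s / frame_interval_s))
  structure(cfg, class = "scene_config")
}

#' Two-pathway conformational state model parameters
#'
#' Discrete-time per-step transition probabilities over the four allowed
#' edges of the activation graph: the canonical (switchblade) pathway
#' `E-H- -> E+H- -> E+H+` and the alternative pathway
#' `E-H- -> E-H+ -> E+H+`.  No reverse transitions are modelled.  The
#' default `E+H- -> E+H+` probability is calibrated so that one third of
#' extended clusters complete activation within four 1-s steps
#' (`1 - (1-q)^4 = 1/3`).  Setting `cis_block = TRUE` models disruption of
#' the cis ICAM interaction that stabilizes the bent-open state: the
#' `E-H+ -> E+H+` rate is multiplied by `cis_factor`, shortening the mean
#' bent-open lifetime from >5 s to <2 s.
#'
#' @param p_bent_to_ext per-step probability of `E-H- -> E+H-`.
#' @param p_bent_to_high per-step probability of `E-H- -> E-H+`.
#' @param p_ext_to_full per-step probability of `E+H- -> E+H+`.
#' @param p_high_to_full per-step probability of `E-H+ -> E+H+`.
#' @param cis_block logical; when TRUE the bent-open state is destabilized.
#' @param cis_factor multiplier applied to `p_high_to_full` under
#'   `cis_block` (capped at probability 1).
#' @return object of class `state_model_params`.
#' @export
state_model_params <- function(p_bent_to_ext = 0.05,
                               p_bent_to_high = 0.05,
                               p_ext_to_full = 1 - (2 / 3)^(1 / 4),
                               p_high_to_full = 0.11,
                               cis_block = FALSE,
                               cis_factor = 5) {
  p <- c(p_bent_to_ext, p_bent_to_high, p_ext_to_full, p_high_to_full)
  if (any(p < 0 | p > 1)) stop_config("transition probabilities must lie in [0, 1]")
  if (p_bent_to_ext + p_bent_to_high > 1) {
    stop_config("competing E-H- exit probabilities must sum to <= 1")
  }
  structure(
    list(p_bent_to_ext = p_bent_to_ext,
         p_bent_to_high = p_bent_to_high,
         p_ext_to_full = p_ext_to_full,
         p_high_to_full = p_high_to_full,
         cis_block = isTRUE(cis_block),
         cis_factor = cis_factor,
         prob_semantics = "per-step"),
    class = "state_model_params"
  )
}

cell_radius_px <- function(config) {
  config$cell_radius_um * 1000 / config$pixel_size_nm
}

#' Build the ground-truth membrane topography of a scene
#'
#' The contact zone is a disk.  A superposition of Gaussian bumps
#' (microvilli) is thresholded at the `hill_fraction` quantile and squashed
#' through a sigmoid, giving a bimodal height field: hills (microvillus
#' tips) near `hill_delta_nm`, valleys near `valley_delta_nm`, with smooth
#' transitions and small within-class variation.  Heights are clipped to
#' `[0, microvillus_height_nm]`; pixels outside the disk are NA.
#'
#' @param config a [scene_config()].
#' @return object of class `scene_topography`: `delta` (nm, cell-frame
#'   patch), `hill`, `disk` (logical matrices), `r_px`, `patch_center`.
#' @export
build_topography <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  r_px <- cell_radius_px(config)
  margin <- 3L
  p <- 2L * ceiling(r_px) + 1L + 2L * margin
  ctr <- (p + 1) / 2
  rows <- matrix(seq_len(p), p, p)
  cols <- matrix(seq_len(p), p, p, byrow = TRUE)
  disk <- (rows - ctr)^2 + (cols - ctr)^2 <= r_px^2
  delta <- matrix(NA_real_, p, p)
  hill <- matrix(FALSE, p, p)
  if (config$hill_fraction == 0) {
    delta[disk] <- config$valley_delta_nm
  } else {
    with_seed(config$rng_seed + 1L, {
      n_bumps <- max(3L, round(sum(disk) / 55))
      theta <- runif(n_bumps, 0, 2 * pi)
      rad <- r_px * sqrt(runif(n_bumps))
      bx <- ctr + rad * cos(theta)
      by <- ctr + rad * sin(theta)
      amp <- runif(n_bumps, 0.7, 1.3)
      sig <- runif(n_bumps, 1.5, 2.6)
      bumps <- matrix(0, p, p)
      for (i in seq_len(n_bumps)) {
        bumps <- bumps + amp[i] *
          exp(-((rows - by[i])^2 + (cols - bx[i])^2) / (2 * sig[i]^2))
      }
      vals <- bumps[disk]
      thr <- stats::quantile(vals, 1 - config$hill_fraction, names = FALSE)
      w <- 0.08 * stats::sd(vals)
      squash <- 1 / (1 + exp(-(bumps - thr) / w))
      rough <- gaussian_blur(matrix(stats::rnorm(p * p), p, p), 2)
      rough <- 1.5 * rough / stats::sd(rough)
      d <- config$valley_delta_nm -
        (config$valley_delta_nm - config$hill_delta_nm) * squash + rough
      d <- pmin(pmax(d, 0), min(config$microvillus_height_nm,
                                config$valley_delta_nm + 4))
      delta[disk] <- d[disk]
      hill <- disk & (bumps >= thr)
    })
  }
  structure(
    list(delta = delta, hill = hill, disk = disk, r_px = r_px,
         patch_center = ctr,
         hill_fraction = if (any(disk)) mean(hill[disk]) else 0),
    class = "scene_topography"
  )
}

#' Build the ground-truth cell trajectory
#'
#' Constant-velocity drift along the image x axis up to the arrest time,
#' stationary afterwards, positioned so that the cell centre sits at the
#' image centre at (and after) arrest.  Gaussian centroid jitter is added
#' per frame (`jitter_sd_um` while rolling, one tenth of it after arrest).
#'
#' @param config a [scene_config()].
#' @return data frame with `frame`, `time_s` (relative to arrest; negative
#'   while rolling), `x_um`, `y_um`.
#' @export
build_cell_track <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$n_frames
  dt <- config$frame_interval_s
  times <- (seq_len(n) - 1) * dt - config$arrest_time_s
  px_um <- config$pixel_size_nm / 1000
  xc <- (config$image_shape[2] + 1) / 2 * px_um
  yc <- (config$image_shape[1] + 1) / 2 * px_um
  x <- xc + config$rolling_velocity_um_s * pmin(times, 0)
  y <- rep(yc, n)
  with_seed(config$rng_seed + 2L, {
    sd_frame <- ifelse(times < 0, config$jitter_sd_um,
                       config$jitter_sd_um / 10)
    x <- x + stats::rnorm(n, 0, sd_frame)
    y <- y + stats::rnorm(n, 0, sd_frame)
  })
  data.frame(frame = seq_len(n), time_s = times, x_um = x, y_um = y)
}

#' Place reporter clusters on the ground-truth topography
#'
#' Each cluster is a connected blob of about `cluster_area_px` pixels grown
#' from a seed pixel; the seed lands on a hill with the class's
#' `hill_bias` probability and growth prefers the seed's terrain, so the
#' cluster's pixel population largely shares the seed's hill/valley
#' character.  Clusters are mutually disjoint with a guard gap of
#' `cluster_buffer_px` pixels.
#'
#' @param config a [scene_config()].
#' @param topography a [build_topography()] result.
#' @return list with `table` (data frame: id, class, seed_on_hill,
#'   area_px, mean_delta_nm, hill_pixel_fraction) and `pixels` (list of
#'   cell-frame linear pixel indices per cluster).
#' @export
init_clusters <- function(config, topography) {
  stopifnot(inherits(config, "scene_config"),
            inherits(topography, "scene_topography"))
  counts <- config$cluster_counts[config$cluster_counts > 0]
  classes <- rep(names(counts), counts)
  n_cl <- length(classes)
  disk <- topography$disk
  hill <- topography$hill
  p <- nrow(disk)
  pixels <- vector("list", n_cl)
  seed_on_hill <- logical(n_cl)
  if (n_cl > 0) {
    with_seed(config$rng_seed + 3L, {
      occ_buf <- matrix(FALSE, p, p)
      for (i in seq_len(n_cl)) {
        bias <- config$hill_bias[[classes[i]]]
        if (is.null(bias)) bias <- 0.5
        done <- FALSE
        for (attempt in seq_len(200L)) {
          want_hill <- stats::runif(1) < bias
          terrain <- if (want_hill) hill else (disk & !hill)
          # prefer seeds interior to a terrain patch so the cluster (and
          # its detection halo) stays on the seed's terrain
          interior <- terrain & !dilate_square(!terrain, 1L)
          avail <- interior & !occ_buf
          if (!any(avail)) avail <- terrain & !occ_buf
          if (!any(avail)) avail <- disk & !occ_buf
          if (!any(avail)) break
          cand <- which(avail)
          seed_px <- cand[sample.int(length(cand), 1L)]
          blob <- matrix(FALSE, p, p)
          blob[seed_px] <- TRUE
          n_blob <- 1L
          allowed <- disk & !occ_buf
          neighbours <- function(px) {
            r <- ((px - 1L) %% p) + 1L
            cc <- ((px - 1L) %/% p) + 1L
            dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
            dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
            r2 <- r + dr
            c2 <- cc + dc
            ok <- r2 >= 1L & r2 <= p & c2 >= 1L & c2 <= p
            (c2[ok] - 1L) * p + r2[ok]
          }
          frontier <- neighbours(seed_px)
          frontier <- frontier[allowed[frontier]]
          while (n_blob < config$cluster_area_px && length(frontier)) {
            frontier <- unique(frontier[!blob[frontier]])
            if (!length(frontier)) break
            pref <- frontier[terrain[frontier]]
            pool <- if (length(pref)) pref else frontier
            pick <- pool[sample.int(length(pool), 1L)]
            blob[pick] <- TRUE
            n_blob <- n_blob + 1L
            frontier <- frontier[frontier != pick]
            nb <- neighbours(pick)
            frontier <- c(frontier, nb[allowed[nb] & !blob[nb]])
          }
          if (n_blob >= config$cluster_area_px) {
            pixels[[i]] <- which(blob)
            seed_on_hill[i] <- hill[seed_px]
            occ_buf <- occ_buf | dilate_square(blob, config$cluster_buffer_px)
            done <- TRUE
            break
          }
        }
        if (!done) {
          stop_config("could not place cluster %d of %d without overlap; %s",
                      i, n_cl, "reduce counts, area or buffer")
        }
      }
    })
  }
  tab <- data.frame(
    id = seq_len(n_cl),
    class = classes,
    seed_on_hill = seed_on_hill,
    area_px = vapply(pixels, length, integer(1)),
    mean_delta_nm = vapply(pixels, function(px) {
      mean(topography$delta[px])
    }, numeric(1)),
    hill_pixel_fraction = vapply(pixels, function(px) {
      mean(hill[px])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(table = tab, pixels = pixels)
}

#' Evolve cluster conformational states over time
#'
#' Discrete-time Markov evolution over the four allowed activation edges
#' (see [state_model_params()]).  Probabilities are interpreted per step of
#' length `dt_s`, as recorded in the `prob_semantics` attribute; they are
#' not rescaled when `dt_s` changes.
#'
#' @param initial_classes character vector of starting classes, one per
#'   cluster (any of `E-H-`, `E+H-`, `E-H+`, `E+H+`).
#' @param params a [state_model_params()].
#' @param n_steps number of frames to simulate (including the initial one).
#' @param dt_s step length in seconds.
#' @param seed optional integer seed for reproducibility.
#' @return list with `classes` (character matrix, clusters x frames),
#'   `events` (data frame: id, from, to, frame, time_s measured from the
#'   first frame) and attribute-like field `prob_semantics`.
#' @export
evolve_states <- function(initial_classes, params, n_steps, dt_s = 1,
                          seed = NULL) {
  stopifnot(inherits(params, "state_model_params"))
  if (!all(initial_classes %in% state_classes())) {
    stop_config("unknown conformation class in initial_classes")
  }
  run <- function() {
    n <- length(initial_classes)
    p_hf <- params$p_high_to_full
    if (params$cis_block) p_hf <- min(1, p_hf * params$cis_factor)
    cls <- matrix(NA_character_, n, n_steps)
    cls[, 1] <- initial_classes
    ev <- list()
    for (f in seq_len(n_steps)[-1]) {
      prev <- cls[, f - 1]
      nxt <- prev
      u <- stats::runif(n)
      i_bent <- prev == "E-H-"
      nxt[i_bent & u < params$p_bent_to_ext] <- "E+H-"
      nxt[i_bent & u >= params$p_bent_to_ext &
            u < params$p_bent_to_ext + params$p_bent_to_high] <- "E-H+"
      nxt[prev == "E+H-" & u < params$p_ext_to_full] <- "E+H+"
      nxt[prev == "E-H+" & u < p_hf] <- "E+H+"
      ch <- which(nxt != prev)
      if (length(ch)) {
        ev[[length(ev) + 1L]] <- data.frame(
          id = ch, from = prev[ch], to = nxt[ch], frame = f,
          time_s = (f - 1) * dt_s, stringsAsFactors = FALSE)
      }
      cls[, f] <- nxt
    }
    events <- if (length(ev)) do.call(rbind, ev) else {
      data.frame(id = integer(), from = character(), to = character(),
                 frame = integer(), time_s = numeric(),
                 stringsAsFactors = FALSE)
    }
    list(classes = cls, events = events, dt_s = dt_s,
         prob_semantics = params$prob_semantics)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete ground-truth scene
#'
#' Couples topography, cell trajectory, cluster placement and state
#' evolution into one ground-truth object consumed by [render_movie()] and
#' by recovery tests.  Everything is deterministic given the configuration.
#'
#' @param config a [scene_config()].
#' @param params a [state_model_params()].
#' @return object of class `qdf_scene` with fields `config`, `params`,
#'   `topography`, `cell_track`, `clusters`, `states`, `event_log` (times
#'   relative to arrest) and `cluster_table` (one row per cluster and
#'   frame, visible classes only).
#' @export
simulate_scene <- function(config = scene_config(),
                           params = state_model_params()) {
  stopifnot(inherits(config, "scene_config"))
  topo <- build_topography(config)
  track <- build_cell_track(config)
  clusters <- init_clusters(config, topo)
  st <- evolve_states(clusters$table$class, params, config$n_frames,
                      dt_s = config$frame_interval_s,
                      seed = config$rng_seed + 4L)
  events <- st$events
  if (nrow(events)) {
    events$time_s <- events$time_s - config$arrest_time_s
  }
  n_cl <- nrow(clusters$table)
  if (n_cl > 0) {
    idx <- expand.grid(id = seq_len(n_cl), frame = seq_len(config$n_frames))
    cluster_table <- data.frame(
      frame = idx$frame,
      time_s = track$time_s[idx$frame],
      id = idx$id,
      class = st$classes[cbind(idx$id, idx$frame)],
      area_px = clusters$table$area_px[idx$id],
      mean_delta_nm = clusters$table$mean_delta_nm[idx$id],
      hill_pixel_fraction = clusters$table$hill_pixel_fraction[idx$id],
      stringsAsFactors = FALSE
    )
    cluster_table <- cluster_table[cluster_table$class != "E-H-", ]
  } else {
    cluster_table <- data.frame(frame = integer(), time_s = numeric(),
                                id = integer(), class = character(),
                                area_px = integer(),
                                mean_delta_nm = numeric(),
                                hill_pixel_fraction = numeric(),
                                stringsAsFactors = FALSE)
  }
  structure(
    list(config = config, params = params, topography = topo,
         cell_track = track, clusters = clusters, states = st,
         event_log = events, cluster_table = cluster_table),
    class = "qdf_scene"
  )
}

#' @export
print.qdf_scene <- function(x, ...) {
  cat(sprintf(
    "qdf_scene: %dx%d px, %d frames (dt = %g s), arrest at frame %d\n",
    x$config$image_shape[1], x$config$image_shape[2], x$config$n_frames,
    x$config$frame_interval_s,
    round(x$config$arrest_time_s / x$config$frame_interval_s) + 1L))
  cat(sprintf("  %d clusters, hill fraction %.3f, %d transition events\n",
              nrow(x$clusters$table), x$topography$hill_fraction,
              nrow(x$event_log)))
  invisible(x)
}

# Integer pixel offset of the cell-frame patch within the image at a frame.
scene_offset <- function(scene, frame) {
  px_um <- scene$config$pixel_size_nm / 1000
  ctr <- scene$topography$patch_center
  c(row = round(scene$cell_track$y_um[frame] / px_um) - ctr,
    col = round(scene$cell_track$x_um[frame] / px_um) - ctr)
}

#' Rasterize the ground truth of one frame into image coordinates
#'
#' @param scene a [simulate_scene()] result.
#' @param frame frame index.
#' @return list with image-coordinate matrices: `delta` (nm, NA outside the
#'   contact zone), `footprint`, `hill` (logicals), `labels` (cluster id
#'   map), `kim`, `mab` (reporter occupancy masks) and the per-cluster
#'   `classes` character vector for this frame.
#' @export
scene_frame_truth <- function(scene, frame) {
  stopifnot(inherits(scene, "qdf_scene"))
  nr <- scene$config$image_shape[1]
  nc <- scene$config$image_shape[2]
  off <- scene_offset(scene, frame)
  p <- nrow(scene$topography$disk)
  delta <- matrix(NA_real_, nr, nc)
  hill <- matrix(FALSE, nr, nc)
  fp <- matrix(FALSE, nr, nc)
  labels <- matrix(0L, nr, nc)
  kim <- matrix(FALSE, nr, nc)
  mab <- matrix(FALSE, nr, nc)
  place <- function(patch_idx) {
    # map cell-frame linear indices to image linear indices (NA off-image)
    r <- ((patch_idx - 1L) %% p) + 1L + off["row"]
    cc <- ((patch_idx - 1L) %/% p) + 1L + off["col"]
    ok <- r >= 1L & r <= nr & cc >= 1L & cc <= nc
    ifelse(ok, (cc - 1L) * nr + r, NA_integer_)
  }
  disk_idx <- which(scene$topography$disk)
  img_idx <- place(disk_idx)
  keep <- !is.na(img_idx)
  delta[img_idx[keep]] <- scene$topography$delta[disk_idx[keep]]
  fp[img_idx[keep]] <- TRUE
  hill_idx <- which(scene$topography$hill)
  hi <- place(hill_idx)
  hill[hi[!is.na(hi)]] <- TRUE
  classes <- scene$states$classes[, frame]
  for (i in seq_along(scene$clusters$pixels)) {
    cl <- classes[i]
    if (cl == "E-H-") next
    ci <- place(scene$clusters$pixels[[i]])
    ci <- ci[!is.na(ci)]
    if (!length(ci)) next
    labels[ci] <- i
    if (cl %in% c("E+H-", "E+H+")) kim[ci] <- TRUE
    if (cl %in% c("E-H+", "E+H+")) mab[ci] <- TRUE
  }
  list(delta = delta, footprint = fp, hill = hill, labels = labels,
       kim = kim, mab = mab, classes = classes)
}
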