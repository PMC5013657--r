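# Pipeline configuration, file formats and stage orchestration.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    thresholds = list(footprint_nm = 95, arrest_um_s = 0.1, reach_nm = 50,
                      transition_window_s = 4),
    optics = list(theta_deg = 70, n_glass = 1.515, n_medium = 1.338,
                  objective_na = 1.45, pixel_size_nm = 64),
    segmentation = list(local_window = 15, k = 3, min_cluster_size = 4,
                        connectivity = 8),
    scene = list(),
    state_model = list()
  )
}

#' Pipeline configuration
#'
#' Collects the analysis constants (95-nm footprint cutoff, 0.1 um/s
#' arrest threshold, 50-nm reach cutoff, 4-s transition window), the
#' optical geometry, segmentation parameters, and any synthetic-scene or
#' state-model overrides, with one seed governing all randomness.
#'
#' @param ... named overrides of the defaults; nested lists (`thresholds`,
#'   `optics`, `segmentation`, `scene`, `state_model`) are merged
#'   per-field.  Unknown keys are rejected.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  merge_pipeline_config(pipeline_defaults(), user)
}

merge_pipeline_config <- function(defaults, user) {
  if (length(user)) {
    if (is.null(names(user)) || any(names(user) == "")) {
      stop_config("pipeline configuration entries must be named")
    }
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop_config("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", "))
    }
    for (key in names(user)) {
      if (is.list(defaults[[key]]) && key %in%
            c("thresholds", "optics", "segmentation")) {
        sub_unknown <- setdiff(names(user[[key]]), names(defaults[[key]]))
        if (length(sub_unknown)) {
          stop_config("unknown configuration key(s): %s",
                      paste(paste(key, sub_unknown, sep = "."),
                            collapse = ", "))
        }
        defaults[[key]][names(user[[key]])] <- user[[key]]
      } else if (key %in% c("scene", "state_model")) {
        allowed <- names(formals(if (key == "scene") scene_config
                                 else state_model_params))
        sub_unknown <- setdiff(names(user[[key]]), allowed)
        if (length(sub_unknown)) {
          stop_config("unknown configuration key(s): %s",
                      paste(paste(key, sub_unknown, sep = "."),
                            collapse = ", "))
        }
        val <- user[[key]]
        # YAML deserializes named vectors as lists; restore them
        for (nm in intersect(c("cluster_counts", "hill_bias",
                               "image_shape"), names(val))) {
          val[[nm]] <- unlist(val[[nm]])
        }
        defaults[[key]] <- val
      } else {
        defaults[[key]] <- user[[key]]
      }
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take their defaults; unknown keys are rejected by name; an
#' empty file yields the full default configuration.  The configuration
#' round-trips losslessly through [save_pipeline_config()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("configuration file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_pipeline_config(pipeline_defaults(), user)
}

#' @rdname load_pipeline_config
#' @param config a [pipeline_config()] to write.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  for (key in c("scene", "state_model")) {
    # named vectors must become maps to keep their names in YAML
    out[[key]] <- lapply(out[[key]], function(v) {
      if (!is.null(names(v)) && is.atomic(v)) as.list(v) else v
    })
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write / read a multichannel movie as multi-page TIFF
#'
#' Pages are ordered frame-major (all channels of frame 1, then frame 2,
#' ...).  Intensities are stored as 16-bit unsigned samples; `max_value`
#' maps to 65535 and is recorded in the `description` tag convention used
#' by [read_movie_tiff()]'s `max_value` argument.
#'
#' @param movie numeric array `[rows, cols, channel, frame]`.
#' @param path output file.
#' @param max_value intensity mapped to the top code (default 65535, i.e.
#'   counts stored directly).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, max_value = 65535) {
  stopifnot(length(dim(movie)) == 4L)
  pages <- list()
  for (f in seq_len(dim(movie)[4])) {
    for (k in seq_len(dim(movie)[3])) {
      pages[[length(pages) + 1L]] <-
        pmin(pmax(movie[, , k, f] / max_value, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param n_channels number of channels interleaved in the file.
#' @param channels channel names for the output array.
#' @export
read_movie_tiff <- function(path, n_channels = 3,
                            channels = c("mab24", "kim127", "membrane"),
                            max_value = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- length(pages) / n_channels
  if (nf != round(nf)) {
    stop_config("page count %d is not a multiple of %d channels",
                length(pages), n_channels)
  }
  nr <- nrow(pages[[1]])
  nc <- ncol(pages[[1]])
  movie <- array(0, dim = c(nr, nc, n_channels, nf),
                 dimnames = list(NULL, NULL, channels[seq_len(n_channels)],
                                 NULL))
  i <- 0L
  for (f in seq_len(nf)) {
    for (k in seq_len(n_channels)) {
      i <- i + 1L
      movie[, , k, f] <- pages[[i]] * max_value
    }
  }
  movie
}

write_table <- function(df, outdir, name) {
  utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
}

pipeline_stages <- function() {
  c("simulate", "heights", "segment", "classify", "track", "localize",
    "quantify")
}

#' Run the footprinting analysis pipeline
#'
#' Executes the requested stages in canonical order:
#' `simulate` (ground-truth scene + rendered movie), `heights`
#' (intensity to height maps and footprint masks), `segment` (reporter
#' clusters, hills/valleys), `classify` (conformation maps and per-class
#' summaries), `track` (cell velocity and arrest, cluster links and
#' transition history), `localize` (hill fractions, reach counts) and
#' `quantify` (summary scalars plus bead-calibration and FRET worked
#' quantities on synthetic fixtures).  Intermediate state is cached in
#' `state.rds` inside `outdir`, so later stages can be re-run alone
#' against an earlier run's outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages subset of the stage names to execute.
#' @return `outdir`, invisibly; artifacts are CSV tables, TIFF stacks, the
#'   effective configuration and a provenance record.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = pipeline_stages()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(outdir, "state.rds")
  state <- if (file.exists(state_path)) readRDS(state_path) else list()

  cfg_path <- file.path(outdir, "config.yaml")
  save_pipeline_config(config, cfg_path)
  yaml::write_yaml(
    list(config_md5 = unname(tools::md5sum(cfg_path)),
         seed = config$seed,
         package = "tqdf",
         version = as.character(utils::packageVersion("tqdf"))),
    file.path(outdir, "provenance.yaml"))

  optics <- do.call(optical_config, config$optics)
  segp <- do.call(segmentation_params, config$segmentation)
  thr <- config$thresholds

  for (stage in stages) {
    state <- switch(stage,
      simulate = stage_simulate(state, config, optics, outdir),
      heights = stage_heights(state, config, optics, thr, outdir),
      segment = stage_segment(state, segp, outdir),
      classify = stage_classify(state, outdir),
      track = stage_track(state, config, thr, outdir),
      localize = stage_localize(state, thr, outdir),
      quantify = stage_quantify(state, config, thr, outdir)
    )
    saveRDS(state, state_path)
  }
  invisible(outdir)
}

stage_simulate <- function(state, config, optics, outdir) {
  scene_args <- config$scene
  scene_args$rng_seed <- config$seed
  scene_args$optics <- optics
  scfg <- do.call(scene_config, scene_args)
  scene <- simulate_scene(scfg, do.call(state_model_params,
                                        config$state_model))
  movie <- render_movie(scene)
  write_movie_tiff(movie, file.path(outdir, "movie.tif"))
  write_table(scene$cell_track, outdir, "truth_cell_track.csv")
  write_table(scene$cluster_table, outdir, "truth_cluster_table.csv")
  write_table(scene$event_log, outdir, "truth_event_log.csv")
  write_table(
    data.frame(hill_fraction = scene$topography$hill_fraction,
               footprint_px = sum(scene$topography$disk),
               n_clusters = nrow(scene$clusters$table)),
    outdir, "truth_topography_stats.csv")
  state$scene <- scene
  state$movie <- movie
  state
}

stage_heights <- function(state, config, optics, thr, outdir) {
  if (is.null(state$movie)) {
    movie_path <- file.path(outdir, "movie.tif")
    if (!file.exists(movie_path)) {
      stop_config(paste("no movie available for the 'heights' stage;",
                        "run 'simulate' first or place movie.tif in %s"),
                  outdir)
    }
    state$movie <- read_movie_tiff(movie_path)
  }
  d_mem <- penetration_depth(optics, "membrane")
  nf <- dim(state$movie)[4]
  hms <- vector("list", nf)
  fps <- vector("list", nf)
  meta <- vector("list", nf)
  for (f in seq_len(nf)) {
    frame <- state$movie[, , "membrane", f]
    est <- tryCatch(estimate_reference_intensity(frame),
                    error = function(e) NULL)
    if (is.null(est)) {
      # nothing above background: cell not (yet) in the field
      hms[f] <- list(NULL)
      fps[[f]] <- matrix(FALSE, nrow(frame), ncol(frame))
      meta[[f]] <- data.frame(frame = f, i0 = NA_real_,
                              background = NA_real_, d_nm = d_mem)
      next
    }
    hm <- intensity_to_height(frame, i0 = est$i0, d = d_mem,
                              background = est$background)
    hms[[f]] <- hm
    fps[[f]] <- footprint_mask(hm, threshold_nm = thr$footprint_nm,
                               min_px = 20)
    meta[[f]] <- data.frame(frame = f, i0 = est$i0,
                            background = est$background, d_nm = d_mem)
  }
  write_table(do.call(rbind, meta), outdir, "heights_frames.csv")
  state$heights <- hms
  state$footprints <- fps
  state
}

stage_segment <- function(state, segp, outdir) {
  if (is.null(state$heights)) {
    stop_config("'segment' needs the 'heights' stage results")
  }
  nf <- length(state$heights)
  kim <- vector("list", nf)
  mab <- vector("list", nf)
  topo <- vector("list", nf)
  hv <- vector("list", nf)
  for (f in seq_len(nf)) {
    fp <- state$footprints[[f]]
    kim[[f]] <- segment_clusters(state$movie[, , "kim127", f], fp, segp)
    mab[[f]] <- segment_clusters(state$movie[, , "mab24", f], fp, segp)
    topo[[f]] <- if (sum(fp) >= 10) {
      segment_hills_valleys(state$heights[[f]], fp)
    } else {
      NULL
    }
    hv[[f]] <- data.frame(
      frame = f,
      footprint_px = sum(fp),
      hill_fraction = if (is.null(topo[[f]])) NA_real_
                      else topo[[f]]$hill_fraction)
  }
  write_table(do.call(rbind, hv), outdir, "hill_fractions.csv")
  state$kim_labels <- kim
  state$mab_labels <- mab
  state$topo <- topo
  state
}

stage_classify <- function(state, outdir) {
  if (is.null(state$kim_labels)) {
    stop_config("'classify' needs the 'segment' stage results")
  }
  nf <- length(state$kim_labels)
  conf <- vector("list", nf)
  union_labels <- vector("list", nf)
  summaries <- vector("list", nf)
  for (f in seq_len(nf)) {
    conf[[f]] <- classify_pixels(state$kim_labels[[f]] > 0L,
                                 state$mab_labels[[f]] > 0L)
    union_labels[[f]] <- label_components(unclass(conf[[f]]) > 0L, 8)
    s <- summarize_classes(conf[[f]])
    s$frame <- f
    summaries[[f]] <- s
  }
  write_table(do.call(rbind, summaries), outdir, "class_summary.csv")
  state$conf <- conf
  state$union_labels <- union_labels
  state
}

stage_track <- function(state, config, thr, outdir) {
  if (is.null(state$conf)) {
    stop_config("'track' needs the 'classify' stage results")
  }
  scfg <- if (!is.null(state$scene)) state$scene$config else NULL
  dt <- if (is.null(scfg)) 1 else scfg$frame_interval_s
  px <- if (is.null(scfg)) config$optics$pixel_size_nm else scfg$pixel_size_nm
  times <- if (is.null(scfg)) {
    (seq_along(state$footprints) - 1) * dt
  } else {
    state$scene$cell_track$time_s
  }
  track <- track_cell(state$footprints, frame_interval_s = dt,
                      pixel_size_nm = px, times_s = times)
  arrest <- detect_arrest(track, threshold_um_s = thr$arrest_um_s)
  offsets <- cbind(row = round(track$y_um * 1000 / px),
                   col = round(track$x_um * 1000 / px))
  offsets[is.na(offsets)] <- 0L
  links <- link_clusters(state$union_labels, offsets_px = offsets)
  history <- transition_history(links, state$union_labels, state$conf,
                                times, window_s = thr$transition_window_s)
  write_table(track, outdir, "cell_track_measured.csv")
  write_table(history$tracks, outdir, "cluster_tracks.csv")
  write_table(history$summary, outdir, "transition_summary.csv")
  state$track <- track
  state$arrest_time <- arrest
  state$links <- links
  state$history <- history
  state
}

stage_localize <- function(state, thr, outdir) {
  if (is.null(state$conf) || is.null(state$topo)) {
    stop_config("'localize' needs the 'segment' and 'classify' stage results")
  }
  nf <- length(state$conf)
  locs <- list()
  for (f in seq_len(nf)) {
    if (is.null(state$topo[[f]])) next
    loc <- localize_clusters(state$union_labels[[f]], state$topo[[f]],
                             state$heights[[f]], conf_map = state$conf[[f]],
                             cutoff_nm = thr$reach_nm)
    if (nrow(loc)) {
      loc$frame <- f
      locs[[length(locs) + 1L]] <- loc
    }
  }
  localizations <- if (length(locs)) do.call(rbind, locs) else {
    data.frame(label = integer(), area_px = integer(),
               hill_pixel_fraction = numeric(), delta_nm = numeric(),
               within_reach = logical(), class = character(),
               frame = integer())
  }
  reach <- if (nrow(localizations)) {
    count_within_reach(localizations, cutoff_nm = thr$reach_nm)
  } else {
    data.frame(frame = integer(), class = character(),
               n_within_reach = integer())
  }
  write_table(localizations, outdir, "cluster_localization.csv")
  write_table(reach, outdir, "reach_counts.csv")
  state$localizations <- localizations
  state$reach <- reach
  state
}

stage_quantify <- function(state, config, thr, outdir) {
  if (is.null(state$track)) {
    stop_config("'quantify' needs the 'track' stage results")
  }
  arrest_frame <- if (is.na(state$arrest_time)) NA_integer_ else {
    which(state$track$time_s == state$arrest_time)[1]
  }
  counts <- rep(NA_integer_, 3)
  if (!is.na(arrest_frame)) {
    s <- summarize_classes(state$conf[[arrest_frame]])
    counts <- s$n_clusters
  }
  # worked molecular quantities on deterministic synthetic fixtures
  panel <- make_bead_panel(noise_sd = 10, n_rep = 3, seed = config$seed + 11L)
  cal <- fit_bead_calibration(panel)
  fretseries <- make_fret_series(noise_sd = 5, seed = config$seed + 12L)
  qg <- quench_gain_stats(fretseries,
                          attr(fretseries, "addition_time_s"))
  spectra <- synthetic_fret_spectra()
  j <- overlap_integral(spectra)
  r0 <- forster_radius(j)
  r <- fret_distance(max(qg$efficiency, 1e-6), r0)
  events <- make_aggregation_events(1000, 1000, 250,
                                    seed = config$seed + 13L)
  summary <- data.frame(
    quantity = c("arrest_time_s", "n_EpHm_at_arrest", "n_EmHp_at_arrest",
                 "n_EpHp_at_arrest", "mean_hill_fraction",
                 "fraction_EpHm_to_full_within_window",
                 "bead_slope", "bead_intercept", "fret_efficiency",
                 "overlap_integral_nm4_M_cm", "forster_radius_nm",
                 "fret_distance_nm", "heteroaggregate_pct"),
    value = c(state$arrest_time, counts[1], counts[2], counts[3],
              {
                hfs <- vapply(state$topo, function(t) {
                  if (is.null(t)) NA_real_ else t$hill_fraction
                }, numeric(1))
                keep <- if (is.na(arrest_frame)) seq_along(hfs) else {
                  seq(arrest_frame, length(hfs))
                }
                mean(hfs[keep], na.rm = TRUE)
              },
              state$history$summary$fraction_within[1],
              cal$slope, cal$intercept, qg$efficiency, j, r0, r,
              heteroaggregate_fraction(events))
  )
  write_table(summary, outdir, "summary.csv")
  state$summary <- summary
  state
}

#' Synthetic donor/acceptor spectra for worked FRET examples
#'
#' Gaussian-shaped stand-ins for a fluorescein-like donor emission
#' spectrum (peak 518 nm) and an orange-dye acceptor absorption spectrum
#' (peak 562 nm, peak molar extinction 1.5e5 / (M cm)).  These are
#' synthetic shapes for demonstrating the overlap-integral machinery, not
#' measured vendor spectra.
#'
#' @param wavelength_nm wavelength grid, nm.
#' @return data frame with `wavelength_nm`, `donor_emission`,
#'   `acceptor_extinction`.
#' @export
synthetic_fret_spectra <- function(wavelength_nm = seq(450, 700, by = 1)) {
  data.frame(
    wavelength_nm = wavelength_nm,
    donor_emission = exp(-(wavelength_nm - 518)^2 / (2 * 18^2)),
    acceptor_extinction = 1.5e5 * exp(-(wavelength_nm - 562)^2 / (2 * 16^2))
  )
}
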