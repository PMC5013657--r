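# Conformation classification, cell tracking (velocity, arrest) and
# cluster tracking (links, transition history, lifetimes).

#' Classify pixels into conformational states from the two reporter masks
#'
#' Pixels positive for the extension reporter only are `E+H-`, for the
#' headpiece reporter only `E-H+`, for both `E+H+`; the three classes
#' partition the union of the two masks.
#'
#' @param kim_mask logical matrix of extension-reporter (KIM127) pixels.
#' @param mab_mask logical matrix of headpiece-reporter (mAb24) pixels.
#' @return integer matrix of class `conformation_map` (0 = none,
#'   1 = `E+H-`, 2 = `E-H+`, 3 = `E+H+`); the code-to-label mapping is in
#'   the `classes` attribute.
#' @export
classify_pixels <- function(kim_mask, mab_mask) {
  stopifnot(is.matrix(kim_mask), is.matrix(mab_mask),
            all(dim(kim_mask) == dim(mab_mask)))
  k <- !is.na(kim_mask) & kim_mask
  m <- !is.na(mab_mask) & mab_mask
  map <- matrix(0L, nrow(k), ncol(k))
  map[k & !m] <- 1L
  map[!k & m] <- 2L
  map[k & m] <- 3L
  structure(map, classes = conformation_classes(),
            class = c("conformation_map", "matrix", "array"))
}

conf_code <- function(cls) match(cls, conformation_classes())

#' Per-frame per-class cluster summary
#'
#' Connected components of the classified pixel map are counted once each
#' under a majority rule: a component's class is the most frequent class
#' among its pixels (ties broken toward the more activated state, i.e.
#' `E+H+` over the single-positive classes).
#'
#' @param conf_map a [classify_pixels()] result.
#' @param connectivity 4 or 8.
#' @return data frame with `class`, `n_clusters`, `total_area_px`,
#'   `mean_size_px` for each of the three classes.
#' @export
summarize_classes <- function(conf_map, connectivity = 8) {
  stopifnot(inherits(conf_map, "conformation_map"))
  labels <- label_components(unclass(conf_map) > 0L, connectivity)
  cls <- conformation_classes()
  n <- stats::setNames(integer(3), cls)
  area <- stats::setNames(integer(3), cls)
  if (max(labels) > 0L) {
    for (id in seq_len(max(labels))) {
      sel <- labels == id
      tab <- tabulate(unclass(conf_map)[sel], nbins = 3L)
      maj <- which(tab == max(tab))
      maj <- maj[length(maj)]  # tie -> highest code (E+H+)
      n[maj] <- n[maj] + 1L
      area[maj] <- area[maj] + sum(sel)
    }
  }
  data.frame(class = cls, n_clusters = unname(n),
             total_area_px = unname(area),
             mean_size_px = unname(ifelse(n > 0, area / n, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Track the cell from its footprint masks
#'
#' Centroid per frame (um), instantaneous velocity (forward difference
#' between consecutive centroids over the frame interval, assigned to the
#' interval's first frame) and cumulative path displacement.
#'
#' @param masks list of logical footprint masks, one per frame (or a 3-D
#'   logical array with frames along the third dimension).
#' @param frame_interval_s acquisition interval, s.
#' @param pixel_size_nm pixel size, nm.
#' @param times_s optional frame times; default `(frame - 1) * interval`.
#' @return data frame of class `cell_track`: `frame`, `time_s`, `x_um`,
#'   `y_um`, `velocity_um_s`, `displacement_um`.  Frames with an empty
#'   mask carry NA coordinates.
#' @export
track_cell <- function(masks, frame_interval_s = 1, pixel_size_nm = 64,
                       times_s = NULL) {
  if (is.array(masks) && length(dim(masks)) == 3L) {
    masks <- lapply(seq_len(dim(masks)[3]), function(f) masks[, , f])
  }
  n <- length(masks)
  px_um <- pixel_size_nm / 1000
  cent <- t(vapply(masks, function(m) {
    m[is.na(m)] <- FALSE
    if (!any(m)) return(c(NA_real_, NA_real_))
    c(mean(col(m)[m]), mean(row(m)[m])) * px_um
  }, numeric(2)))
  if (is.null(times_s)) times_s <- (seq_len(n) - 1) * frame_interval_s
  step <- sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2)
  vel <- c(step / diff(times_s), NA_real_)
  disp <- c(0, cumsum(ifelse(is.na(step), 0, step)))
  out <- data.frame(frame = seq_len(n), time_s = times_s,
                    x_um = cent[, 1], y_um = cent[, 2],
                    velocity_um_s = vel, displacement_um = disp)
  class(out) <- c("cell_track", "data.frame")
  out
}

#' Detect cell arrest from a velocity trace
#'
#' Arrest is the first time the velocity drops below `threshold_um_s`
#' (default 0.1 um/s) and stays below it for `confirm_frames` consecutive
#' frames, which guards against single-frame tracking noise.  A run
#' truncated by the end of the track still counts if every remaining
#' velocity is below threshold.
#'
#' @param track a [track_cell()] data frame (or any data frame with
#'   `time_s` and `velocity_um_s`).
#' @param threshold_um_s arrest velocity threshold, um/s.
#' @param confirm_frames confirmation window length in frames (default 3).
#' @return arrest time in the track's time units, or `NA` if the cell
#'   never arrests.
#' @export
detect_arrest <- function(track, threshold_um_s = 0.1, confirm_frames = 3) {
  stopifnot(is.data.frame(track),
            all(c("time_s", "velocity_um_s") %in% names(track)))
  v <- track$velocity_um_s
  below <- !is.na(v) & v < threshold_um_s
  n <- length(below)
  for (i in seq_len(n)) {
    if (!below[i]) next
    j <- min(n, i + confirm_frames - 1L)
    if (all(below[i:j])) return(track$time_s[i])
  }
  NA_real_
}

#' Link clusters across frames by pixel overlap
#'
#' Greedy frame-to-frame association: after compensating the cell's
#' centroid motion, candidate pairs are ranked by overlap fraction
#' (shared pixels over the smaller cluster's area) and matched one-to-one
#' while the fraction is at least `min_overlap`.  Unmatched clusters start
#' or terminate tracks.
#'
#' @param label_maps list of integer cluster label matrices, one per frame.
#' @param offsets_px optional matrix/data frame of per-frame integer pixel
#'   offsets (columns `row`, `col`) of the cell, used to align frames
#'   before computing overlaps; default no compensation.
#' @param min_overlap minimum overlap fraction (default 0.3).
#' @return data frame with `track_id`, `frame`, `label` giving the cluster
#'   label carried by each track in each frame it is present.
#' @export
link_clusters <- function(label_maps, offsets_px = NULL, min_overlap = 0.3) {
  n <- length(label_maps)
  stopifnot(n >= 1)
  if (is.null(offsets_px)) {
    offsets_px <- matrix(0L, n, 2, dimnames = list(NULL, c("row", "col")))
  }
  offsets_px <- as.matrix(offsets_px)
  nr <- nrow(label_maps[[1]])
  # labelled pixels keyed by cell-aligned coordinates
  aligned <- function(f) {
    lm <- label_maps[[f]]
    px <- which(lm > 0L)
    r <- ((px - 1L) %% nr) - offsets_px[f, 1]
    cc <- ((px - 1L) %/% nr) - offsets_px[f, 2]
    list(key = r + cc * 2e5, label = lm[px],
         area = tabulate(lm[px]))
  }
  prev <- aligned(1L)
  rows <- list()
  prev_ids <- sort(unique(prev$label))
  track_of <- integer(max(prev$label, 0L))
  track_of[prev_ids] <- seq_along(prev_ids)
  next_track <- length(prev_ids)
  for (id in prev_ids) {
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = track_of[id], frame = 1L, label = id)
  }
  for (f in seq_len(n)[-1]) {
    cur <- aligned(f)
    cur_ids <- sort(unique(cur$label))
    pairs <- NULL
    if (length(prev$key) && length(cur$key)) {
      hit <- match(prev$key, cur$key)
      ok <- !is.na(hit)
      if (any(ok)) {
        a <- prev$label[ok]
        b <- cur$label[hit[ok]]
        ov <- stats::aggregate(rep(1L, length(a)),
                               by = list(a = a, b = b), FUN = sum)
        ov$frac <- ov$x / pmin(prev$area[ov$a], cur$area[ov$b])
        pairs <- ov[ov$frac >= min_overlap, , drop = FALSE]
        pairs <- pairs[order(-pairs$frac, pairs$a, pairs$b), , drop = FALSE]
      }
    }
    new_track_of <- integer(max(cur$label, 0L))
    used_a <- logical(length(track_of))
    if (!is.null(pairs) && nrow(pairs)) {
      for (i in seq_len(nrow(pairs))) {
        a <- pairs$a[i]
        b <- pairs$b[i]
        if (used_a[a] || new_track_of[b] != 0L) next
        new_track_of[b] <- track_of[a]
        used_a[a] <- TRUE
      }
    }
    for (b in cur_ids) {
      if (new_track_of[b] == 0L) {
        next_track <- next_track + 1L
        new_track_of[b] <- next_track
      }
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = new_track_of[b], frame = f, label = b)
    }
    prev <- cur
    track_of <- new_track_of
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Colour-transition history of tracked clusters
#'
#' For every track: the initial class (majority class of its pixels when
#' first observed), the time the first fully activated (`E+H+`) pixel
#' appears inside the cluster, and the resulting duration since first
#' observation.  The cohort summary reports, per initial class, the
#' fraction of tracks that acquired `E+H+` pixels within `window_s`
#' seconds.
#'
#' @param links a [link_clusters()] data frame.
#' @param label_maps list of integer cluster label matrices per frame.
#' @param conf_maps list of [classify_pixels()] maps per frame.
#' @param times_s frame times in seconds.
#' @param window_s transition window for the cohort summary (default 4 s).
#' @return list with `tracks` (per-track data frame: `track_id`,
#'   `first_frame`, `t0_s`, `initial_class`, `t_full_s`, `duration_s`) and
#'   `summary` (per initial class: `n`, `n_within`, `fraction_within`).
#' @export
transition_history <- function(links, label_maps, conf_maps, times_s,
                               window_s = 4) {
  cls <- conformation_classes()
  track_ids <- unique(links$track_id)
  tracks <- do.call(rbind, lapply(track_ids, function(tid) {
    seg <- links[links$track_id == tid, , drop = FALSE]
    comp_codes <- function(i) {
      f <- seg$frame[i]
      px <- label_maps[[f]] == seg$label[i]
      unclass(conf_maps[[f]])[px]
    }
    codes0 <- comp_codes(1L)
    tab <- tabulate(codes0[codes0 > 0], nbins = 3L)
    initial <- if (sum(tab) == 0) NA_character_ else {
      maj <- which(tab == max(tab))
      cls[maj[length(maj)]]
    }
    t_full <- NA_real_
    for (i in seq_len(nrow(seg))) {
      if (any(comp_codes(i) == 3L)) {
        t_full <- times_s[seg$frame[i]]
        break
      }
    }
    data.frame(track_id = tid, first_frame = seg$frame[1],
               t0_s = times_s[seg$frame[1]], initial_class = initial,
               t_full_s = t_full,
               duration_s = t_full - times_s[seg$frame[1]],
               stringsAsFactors = FALSE)
  }))
  single <- c("E+H-", "E-H+")
  summary <- do.call(rbind, lapply(single, function(cl) {
    sel <- tracks[!is.na(tracks$initial_class) &
                    tracks$initial_class == cl, , drop = FALSE]
    within <- !is.na(sel$duration_s) & sel$duration_s <= window_s &
      sel$duration_s > 0
    data.frame(initial_class = cl, n = nrow(sel), n_within = sum(within),
               fraction_within = if (nrow(sel)) sum(within) / nrow(sel)
                                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(tracks = tracks, summary = summary, window_s = window_s)
}

#' Lifetime of a cluster before full activation
#'
#' Time from a cluster's first observation to the first appearance of a
#' fully activated (`E+H+`) state, computed from a per-frame class
#' sequence.  `NA` if the cluster never acquires `E+H+`; 0 if it is
#' already `E+H+` when first observed.
#'
#' @param classes character vector (or matrix, clusters in rows) of
#'   per-frame classes; `NA` or `"E-H-"` entries mean not yet visible.
#' @param times_s frame times in seconds.
#' @return numeric duration(s) in seconds.
#' @export
cluster_duration <- function(classes, times_s) {
  one <- function(cl) {
    vis <- which(!is.na(cl) & cl != "E-H-")
    if (!length(vis)) return(NA_real_)
    t0 <- times_s[vis[1]]
    full <- vis[cl[vis] == "E+H+"]
    if (!length(full)) return(NA_real_)
    times_s[full[1]] - t0
  }
  if (is.matrix(classes)) {
    apply(classes, 1, one)
  } else {
    one(classes)
  }
}
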