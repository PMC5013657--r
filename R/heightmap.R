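#' Height map container
#'
#' Per-pixel distance of the cell membrane from the total-internal-reflection
#' interface, in nm, together with a validity mask.  Heights are only
#' trusted within `max_depth_nm` (default 200 nm) of the interface; pixels
#' at or below background, or mapping beyond the validity range, are marked
#' invalid.
#'
#' @param delta numeric matrix of heights in nm (NA where invalid).
#' @param valid logical matrix, same shape.
#' @param i0 reference intensity (counts at zero height above background).
#' @param d penetration depth in nm.
#' @param background background level subtracted, counts.
#' @param max_depth_nm validity range of the height reconstruction.
#' @return an object of class `height_map`.
#' @export
height_map <- function(delta, valid, i0, d, background,
                       max_depth_nm = 200) {
  stopifnot(is.matrix(delta), is.matrix(valid),
            all(dim(delta) == dim(valid)))
  structure(
    list(delta = delta, valid = valid, i0 = i0, d = d,
         background = background, max_depth_nm = max_depth_nm),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "height_map: %d x %d px, d = %.1f nm, I0 = %.1f, background = %.1f\n",
    nrow(x$delta), ncol(x$delta), x$d, x$i0, x$background))
  cat(sprintf("  valid: %d px, height range %.1f-%.1f nm\n",
              sum(x$valid),
              suppressWarnings(min(x$delta[x$valid])),
              suppressWarnings(max(x$delta[x$valid]))))
  invisible(x)
}

#' Estimate the zero-height reference intensity of a membrane frame
#'
#' The evanescent-field inversion needs the intensity `I0` that a membrane
#' patch at the interface (height 0) would emit.  When no instrument
#' calibration is available it is estimated as a high quantile of the
#' background-subtracted intensities of footprint-candidate pixels
#' (pixels exceeding background by `k_mad` robust standard deviations).
#' A user-supplied `fixed_i0` bypasses estimation and is returned as-is.
#'
#' @param frame numeric matrix, membrane-channel intensities (counts).
#' @param background scalar background level; by default estimated from the
#'   dark tail of the frame: the 5th/20th percentiles give the location and
#'   noise scale of the off-cell background population (valid whenever at
#'   least ~20% of the field is off-cell), and the background is the
#'   implied population centre.
#' @param probs quantile used for the estimate (default 0.995).
#' @param k_sigma signal cutoff in background-noise SDs (default 5); the
#'   reference intensity is the `probs` quantile of the
#'   background-subtracted intensities of signal pixels.
#' @param min_signal_px minimum number of signal pixels required; fewer
#'   raises an estimation error (no cell in the frame).
#' @param fixed_i0 optional known reference intensity; returned unchanged.
#' @return list with `i0`, `background`, `sigma`, `method`, `probs`.
#' @export
estimate_reference_intensity <- function(frame, background = NULL,
                                         probs = 0.995, k_sigma = 5,
                                         min_signal_px = 10,
                                         fixed_i0 = NULL) {
  stopifnot(is.matrix(frame))
  vals <- frame[!is.na(frame)]
  q <- stats::quantile(vals, c(0.05, 0.20), names = FALSE)
  sigma <- (q[2] - q[1]) / (stats::qnorm(0.20) - stats::qnorm(0.05))
  if (is.null(background)) {
    background <- q[1] + 1.645 * sigma  # recentre the dark-tail quantile
  }
  if (!is.null(fixed_i0)) {
    return(list(i0 = fixed_i0, background = background, sigma = sigma,
                method = "fixed", probs = NA_real_))
  }
  resid <- frame - background
  cand <- resid[!is.na(resid) & resid > k_sigma * sigma]
  if (length(cand) < min_signal_px) {
    stop_config("cannot estimate reference intensity: no pixels above background")
  }
  list(i0 = unname(stats::quantile(cand, probs)), background = background,
       sigma = sigma, method = "quantile", probs = probs)
}

#' Convert membrane-channel intensity to a height map
#'
#' Inverts the exponential evanescent-field decay:
#' `delta = d * ln(I0 / (I - background))`.  Pixels brighter than `I0`
#' (membrane at the interface) are clipped to height 0; pixels at or below
#' background, or with reconstructed height beyond `max_depth_nm`, are
#' marked invalid rather than extrapolated.
#'
#' @param frame numeric matrix of membrane intensities (counts).
#' @param i0 reference intensity above background at height 0 (counts).
#' @param d penetration depth in nm, see [penetration_depth()].
#' @param background background level (counts), subtracted before the log.
#' @param max_depth_nm validity range (default 200 nm).
#' @return a [height_map()].
#' @examples
#' f <- matrix(100 + 2000 * exp(-c(0, 40, 80, 300) / 80), 1)
#' intensity_to_height(f, i0 = 2000, d = 80, background = 100)$delta
#' @export
intensity_to_height <- function(frame, i0, d, background = 0,
                                max_depth_nm = 200) {
  stopifnot(is.matrix(frame))
  if (d <= 0) stop_config("penetration depth d must be positive")
  if (i0 <= 0) stop_config("reference intensity i0 must be positive")
  net <- frame - background
  pos <- !is.na(net) & net > 0
  delta <- matrix(NA_real_, nrow(frame), ncol(frame))
  delta[pos] <- d * log(i0 / net[pos])
  delta[pos & delta < 0] <- 0
  valid <- pos & !is.na(delta) & delta <= max_depth_nm
  delta[!valid] <- NA_real_
  height_map(delta, valid, i0 = i0, d = d, background = background,
             max_depth_nm = max_depth_nm)
}

#' Footprint mask from a height map
#'
#' The cell footprint is the region of the height map within `threshold_nm`
#' (default 95 nm) of the interface.  By default only the largest connected
#' component is kept, dropping background satellites not associated with
#' the footprint.
#'
#' @param hm a [height_map()].
#' @param threshold_nm footprint height cutoff in nm (default 95).
#' @param keep_largest drop all but the largest connected component.
#' @param connectivity 4 or 8 (default 8).
#' @param min_px smallest footprint accepted, px; a largest component below
#'   this size (e.g. a noise satellite in a frame without a cell) yields an
#'   empty mask.
#' @return logical matrix with attribute `threshold_nm`.
#' @export
footprint_mask <- function(hm, threshold_nm = 95, keep_largest = TRUE,
                           connectivity = 8, min_px = 0) {
  stopifnot(inherits(hm, "height_map"))
  mask <- hm$valid & !is.na(hm$delta) & hm$delta <= threshold_nm
  mask[is.na(mask)] <- FALSE
  if (keep_largest && any(mask)) {
    mask <- largest_component(mask, connectivity)
  }
  if (sum(mask) < min_px) {
    mask[] <- FALSE
  }
  attr(mask, "threshold_nm") <- threshold_nm
  mask
}

#' One-pixel outline of a binary mask
#'
#' Mask pixels with at least one 4-neighbour outside the mask (image
#' borders count as outside), giving the one-pixel-wide footprint boundary.
#'
#' @param mask logical matrix.
#' @return logical matrix of boundary pixels.
#' @export
footprint_outline <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask
  m[is.na(m)] <- FALSE
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  interior <- core &
    pad[1:nr, 2:(nc + 1L), drop = FALSE] &
    pad[3:(nr + 2L), 2:(nc + 1L), drop = FALSE] &
    pad[2:(nr + 1L), 1:nc, drop = FALSE] &
    pad[2:(nr + 1L), 3:(nc + 2L), drop = FALSE]
  m & !interior
}
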