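# Localization of clusters on the footprint topography and relative to
# the substrate ("within reach" of trans ligand).

#' Localize clusters on hills/valleys and relative to the substrate
#'
#' For every labelled cluster: the fraction of its pixels on hills, its
#' summary height above the interface, and whether it is within ligand
#' reach of the substrate (height at most `cutoff_nm`, boundary
#' inclusive).  The height summary is the cluster's mean height by
#' default; `stat = "min"` uses the closest pixel instead.
#'
#' @param labels integer cluster label matrix.
#' @param topo a [segment_hills_valleys()] result (or an integer matrix
#'   with 1 = hill, 2 = valley).
#' @param hm a [height_map()] (or a bare numeric height matrix, nm).
#' @param conf_map optional [classify_pixels()] map; adds a majority
#'   `class` column.
#' @param cutoff_nm reach cutoff, nm (default 50).
#' @param stat `"mean"` (default) or `"min"` cluster height summary.
#' @return data frame with one row per cluster: `label`, `area_px`,
#'   `hill_pixel_fraction`, `delta_nm`, `within_reach`, and `class` when
#'   `conf_map` is given.
#' @export
localize_clusters <- function(labels, topo, hm, conf_map = NULL,
                              cutoff_nm = 50, stat = c("mean", "min")) {
  stat <- match.arg(stat)
  tmap <- if (inherits(topo, "topography_map")) topo$map else topo
  delta <- if (inherits(hm, "height_map")) hm$delta else hm
  stopifnot(is.matrix(labels), all(dim(labels) == dim(tmap)),
            all(dim(labels) == dim(delta)))
  ids <- sort(unique(labels[labels > 0L]))
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    inside <- sel & tmap > 0L
    hill_frac <- if (any(inside)) mean(tmap[inside] == 1L) else NA_real_
    dvals <- delta[sel]
    dvals <- dvals[!is.na(dvals)]
    d <- if (!length(dvals)) NA_real_
         else if (stat == "mean") mean(dvals) else min(dvals)
    data.frame(label = id, area_px = sum(sel),
               hill_pixel_fraction = hill_frac, delta_nm = d,
               within_reach = !is.na(d) & d <= cutoff_nm)
  }))
  if (is.null(out)) {
    out <- data.frame(label = integer(), area_px = integer(),
                      hill_pixel_fraction = numeric(), delta_nm = numeric(),
                      within_reach = logical())
  }
  if (!is.null(conf_map) && nrow(out)) {
    cls <- conformation_classes()
    out$class <- vapply(out$label, function(id) {
      codes <- unclass(conf_map)[labels == id]
      tab <- tabulate(codes[codes > 0], nbins = 3L)
      if (sum(tab) == 0) return(NA_character_)
      maj <- which(tab == max(tab))
      cls[maj[length(maj)]]
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' Count clusters within ligand reach, per frame and class
#'
#' @param localizations a data frame of [localize_clusters()] rows, with
#'   `delta_nm` and optionally `frame` and `class` columns to group by.
#' @param cutoff_nm reach cutoff, nm (default 50, boundary inclusive).
#' @return data frame with the grouping columns present in the input and
#'   `n_within_reach`.
#' @export
count_within_reach <- function(localizations, cutoff_nm = 50) {
  stopifnot(is.data.frame(localizations), "delta_nm" %in% names(localizations))
  within <- !is.na(localizations$delta_nm) &
    localizations$delta_nm <= cutoff_nm
  by_cols <- intersect(c("frame", "class"), names(localizations))
  if (!length(by_cols)) {
    return(data.frame(n_within_reach = sum(within)))
  }
  agg <- stats::aggregate(within, by = localizations[by_cols], FUN = sum)
  names(agg)[ncol(agg)] <- "n_within_reach"
  agg[do.call(order, agg[by_cols]), , drop = FALSE]
}

#' Linear time trend of the hill fraction
#'
#' Least-squares slope of per-frame hill fractions against time, with the
#' F-test of the slope against zero (see [slope_test()]).
#'
#' @param fractions per-frame hill fractions.
#' @param times_s frame times, s.
#' @return a [slope_test()] result.
#' @export
hill_fraction_trend <- function(fractions, times_s) {
  slope_test(times_s, fractions)
}
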