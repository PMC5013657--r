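# Internal helpers shared across modules.

#' Label connected components of a binary mask
#'
#' Flood-fill labelling of the foreground (non-zero, non-NA) pixels of a
#' matrix.  Labels are assigned in column-major scan order of the first pixel
#' reached, so the result is fully deterministic.
#'
#' @param mask logical or numeric matrix; non-zero pixels are foreground.
#' @param connectivity 4 (edge neighbours) or 8 (edge + corner neighbours).
#' @return integer matrix of the same shape; 0 is background, components are
#'   numbered 1..n.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8")
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  fgv <- !is.na(mask) & (mask != 0)
  lab <- integer(nr * nc)
  fg <- which(fgv)
  if (length(fg) == 0L) {
    return(matrix(lab, nr, nc))
  }
  use8 <- connectivity == 8L
  queue <- integer(length(fg))
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      p <- queue[head]
      head <- head + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dc in -1L:1L) {
        c2 <- cc + dc
        if (c2 < 1L || c2 > nc) next
        for (dr in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          if (!use8 && dr != 0L && dc != 0L) next
          r2 <- r + dr
          if (r2 < 1L || r2 > nr) next
          q <- (c2 - 1L) * nr + r2
          if (lab[q] == 0L && fgv[q]) {
            lab[q] <- cur
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  matrix(lab, nr, nc)
}

#' Keep only the largest connected component of a mask
#'
#' Ties are broken toward the component first reached in scan order.
#'
#' @inheritParams label_components
#' @return logical matrix.
#' @export
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  }
  sizes <- tabulate(lab)
  lab == which.max(sizes)
}

# Relabel a label matrix so labels are 1..n in scan order of first pixel.
relabel_sequential <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (length(ids) == 0L) return(lab)
  out <- lab
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# Binary dilation with a (2r+1)x(2r+1) square structuring element.
dilate_square <- function(mask, r = 1L) {
  if (r <= 0L) return(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -r:r) {
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    for (dc in -r:r) {
      cs <- max(1L, 1L - dc):min(nc, nc - dc)
      out[rs + dr, cs + dc] <- out[rs + dr, cs + dc] | mask[rs, cs]
    }
  }
  out
}

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# Otsu threshold (between-class variance maximization) on a numeric vector.
# Returns NA when the values are (near-)constant.
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(NA_real_)
  }
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, brk, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Gaussian blur wrapper returning a plain matrix; sigma <= 0 is a no-op.
gaussian_blur <- function(m, sigma) {
  if (is.null(sigma) || sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
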