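# Regression slope tests and three-model histogram fitting.

#' Test a regression slope against zero
#'
#' Ordinary least squares of `y` on `x` with the F-test of the slope
#' against zero (equivalently the square of the slope's t statistic).
#' Degenerate inputs (zero residual variance) are resolved exactly: a flat
#' perfect fit gives p = 1, a sloped perfect fit p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `slope`, `intercept`, `slope_se`, `f_statistic`,
#'   `df`, `p_value`.
#' @export
slope_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  df2 <- fit$df.residual
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((x - mean(x))^2)
  if (rss <= .Machine$double.eps * max(1, sum(y^2))) {
    flat <- abs(co[["x"]]) < sqrt(.Machine$double.eps) * max(1, abs(co[[1]]))
    return(list(slope = unname(co[["x"]]), intercept = unname(co[[1]]),
                slope_se = 0,
                f_statistic = if (flat) 0 else Inf, df = c(1, df2),
                p_value = if (flat) 1 else 0))
  }
  se <- sqrt(rss / df2 / sxx)
  f <- (co[["x"]] / se)^2
  list(slope = unname(co[["x"]]), intercept = unname(co[[1]]),
       slope_se = se, f_statistic = unname(f), df = c(1, df2),
       p_value = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Compare the slopes of two regressions
#'
#' Nested-model F-test of a common slope: the full model fits separate
#' slopes per data set (`y ~ x * group`), the reduced model a shared slope
#' (`y ~ x + group`).
#'
#' @param x1,y1 first data set.
#' @param x2,y2 second data set.
#' @return list with `slope1`, `slope2`, `f_statistic`, `df`, `p_value`.
#' @export
compare_slopes <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2))
  dat <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = factor(rep(c("a", "b"), c(length(x1), length(x2)))))
  full <- stats::lm(y ~ x * g, data = dat)
  red <- stats::lm(y ~ x + g, data = dat)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  df2 <- full$df.residual
  scale <- max(1, sum(dat$y^2))
  if (rss_f <= .Machine$double.eps * scale) {
    # perfect separate fits: equal slopes -> identical models, p = 1
    same <- rss_r <= .Machine$double.eps * scale
    f <- if (same) 0 else Inf
    p <- if (same) 1 else 0
  } else {
    f <- (rss_r - rss_f) / (rss_f / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  co <- stats::coef(full)
  list(slope1 = unname(co[["x"]]),
       slope2 = unname(co[["x"]] + co[["x:gb"]]),
       f_statistic = f, df = c(1, df2), p_value = p)
}

hist_models <- list(
  gaussian = list(
    f = function(x, p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)),
    start = function(x, y) {
      mu <- sum(x * y) / sum(y)
      s <- sqrt(sum(y * (x - mu)^2) / sum(y))
      c(A = max(y), mu = mu, s = max(s, 1e-3))
    },
    location = function(p) unname(p[2])
  ),
  log_gaussian = list(
    f = function(x, p) {
      out <- numeric(length(x))
      ok <- x > 0
      out[ok] <- p[1] * exp(-(log(x[ok]) - p[2])^2 / (2 * p[3]^2))
      out
    },
    start = function(x, y) {
      ok <- x > 0 & y > 0
      mu <- sum(log(x[ok]) * y[ok]) / sum(y[ok])
      s <- sqrt(sum(y[ok] * (log(x[ok]) - mu)^2) / sum(y[ok]))
      c(A = max(y), mu = mu, s = max(s, 1e-3))
    },
    location = function(p) unname(exp(p[2]))  # peak of the shape in x
  ),
  lorentzian = list(
    f = function(x, p) p[1] / (1 + ((x - p[2]) / p[3])^2),
    start = function(x, y) {
      x0 <- x[which.max(y)]
      half <- y >= max(y) / 2
      g <- max(diff(range(x[half])) / 2, mean(diff(x)) / 2)
      c(A = max(y), x0 = x0, g = g)
    },
    location = function(p) unname(p[2])
  )
)

#' Fit duration histograms with Gaussian, log-Gaussian and Lorentzian models
#'
#' Bins the durations at `bin_width_s`, least-squares fits each of the
#' three peak models to the bin counts, and selects the best model by
#' residual sum of squares.
#'
#' @param durations_s numeric vector of durations, s.
#' @param bin_width_s histogram bin width, s (default 1).
#' @return object of class `duration_histogram_fit`: `histogram` (data
#'   frame of bin mids and counts), `fits` (per model: parameters, `rss`,
#'   `location` (model peak), `curve_mean` (mean of the fitted curve over
#'   the histogram support, a robust scale for decaying histograms),
#'   `converged`), `best` (model name minimizing RSS).
#' @export
fit_duration_histogram <- function(durations_s, bin_width_s = 1) {
  durations_s <- durations_s[is.finite(durations_s)]
  if (!length(durations_s)) stop_config("no finite durations to fit")
  breaks <- seq(floor(min(durations_s) / bin_width_s) * bin_width_s,
                max(durations_s) + bin_width_s, by = bin_width_s)
  h <- graphics::hist(durations_s, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  if (sum(y > 0) < 5L) {
    stop_config(paste("histogram has only %d non-empty bins (< 5);",
                      "too few for a three-parameter fit"), sum(y > 0))
  }
  fits <- lapply(names(hist_models), function(name) {
    m <- hist_models[[name]]
    p0 <- m$start(x, y)
    res <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = p0,
        fn = function(p) y - m$f(x, p),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- stats::coef(fit)
      yhat <- pmax(m$f(x, p), 0)
      list(parameters = p, rss = sum((y - m$f(x, p))^2),
           location = m$location(p),
           curve_mean = if (sum(yhat) > 0) sum(x * yhat) / sum(yhat)
                        else NA_real_,
           converged = TRUE)
    }, error = function(e) {
      list(parameters = p0, rss = Inf, location = NA_real_,
           curve_mean = NA_real_, converged = FALSE)
    })
    res
  })
  names(fits) <- names(hist_models)
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  structure(
    list(histogram = data.frame(mid_s = x, count = y), fits = fits,
         best = names(which.min(rss)), bin_width_s = bin_width_s),
    class = "duration_histogram_fit"
  )
}

#' @export
print.duration_histogram_fit <- function(x, ...) {
  cat(sprintf("duration histogram fit (bin = %g s): best model = %s\n",
              x$bin_width_s, x$best))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-12s rss = %10.3f  location = %6.2f s%s\n", nm, f$rss,
                f$location, if (f$converged) "" else "  (not converged)"))
  }
  invisible(x)
}

#' Two-group t-test and chi-square wrappers
#'
#' Thin delegations to [stats::t.test()] and [stats::chisq.test()] so the
#' pipeline's statistical surface is complete; nothing is re-derived.
#'
#' @param x,y group values (t-test) .
#' @param paired paired t-test flag.
#' @param ... passed through.
#' @return the underlying `htest` object.
#' @export
two_group_test <- function(x, y, paired = FALSE, ...) {
  stats::t.test(x, y, paired = paired, ...)
}

#' @rdname two_group_test
#' @param table contingency table for the chi-square test.
#' @export
count_table_test <- function(table, ...) {
  stats::chisq.test(table, ...)
}
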