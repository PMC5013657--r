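# Synthetic flow-cytometry fixtures: calibration beads, FRET time series
# and two-colour aggregation event tables, all with known ground truth.

#' Simulate a calibration-bead panel
#'
#' Bead populations with known antibody-binding capacities (ABC) and a
#' linear fluorescence response `MFI = intercept + slope * ABC + noise`,
#' mimicking quantitation standards measured alongside stained cells.
#'
#' @param slope true counts per binding site.
#' @param intercept true background MFI, counts.
#' @param abc_levels known antibody-binding capacities (>= 2 distinct
#'   levels; five-level default).
#' @param noise_sd Gaussian MFI noise SD.
#' @param n_rep replicates per level.
#' @param seed optional integer seed.
#' @return data frame with `abc` and `mfi`.
#' @export
make_bead_panel <- function(slope = 0.02, intercept = 5,
                            abc_levels = c(0, 5e3, 2e4, 5e4, 1e5),
                            noise_sd = 0, n_rep = 1, seed = NULL) {
  if (length(unique(abc_levels)) < 2L) {
    stop_config("bead panel needs at least 2 distinct ABC levels")
  }
  abc <- rep(abc_levels, each = n_rep)
  gen <- function() {
    data.frame(abc = abc,
               mfi = intercept + slope * abc +
                 stats::rnorm(length(abc), 0, noise_sd))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a FRET donor/acceptor time series
#'
#' Donor fluorescence starts at `f_d`, and after the acceptor is added at
#' `addition_time_s` decays as a saturating exponential to the quenched
#' plateau `f_d * (1 - true_e)`.  The acceptor trace rises correspondingly
#' from its baseline by `acceptor_gain * f_d * true_e`.
#'
#' @param true_e true FRET efficiency in [0, 1).
#' @param f_d unquenched donor intensity.
#' @param acceptor_baseline acceptor intensity before the donor transfer.
#' @param acceptor_gain fraction of the transferred donor signal appearing
#'   in the acceptor detection window.
#' @param addition_time_s time the acceptor is added, s.
#' @param duration_s trace length, s.
#' @param dt_s sampling interval, s.
#' @param tau_s time constant of the saturating approach to plateau, s.
#' @param noise_sd Gaussian noise SD on both traces.
#' @param seed optional integer seed.
#' @return data frame with `time_s`, `donor`, `acceptor`; attributes
#'   `true_e` and `addition_time_s`.
#' @export
make_fret_series <- function(true_e = 0.3, f_d = 1000,
                             acceptor_baseline = 200, acceptor_gain = 0.5,
                             addition_time_s = 10, duration_s = 240,
                             dt_s = 1, tau_s = 20, noise_sd = 0,
                             seed = NULL) {
  if (true_e < 0 || true_e >= 1) stop_config("true_e must lie in [0, 1)")
  t <- seq(0, duration_s, by = dt_s)
  rise <- ifelse(t < addition_time_s, 0,
                 1 - exp(-(t - addition_time_s) / tau_s))
  gen <- function() {
    data.frame(
      time_s = t,
      donor = f_d - f_d * true_e * rise +
        stats::rnorm(length(t), 0, noise_sd),
      acceptor = acceptor_baseline + acceptor_gain * f_d * true_e * rise +
        stats::rnorm(length(t), 0, noise_sd)
    )
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  attr(out, "true_e") <- true_e
  attr(out, "addition_time_s") <- addition_time_s
  out
}

#' Simulate a two-colour aggregation event table
#'
#' Events from two dye-labelled cell populations and their
#' hetero-aggregates: single-green events are bright only in the green
#' channel, single-orange only in the orange channel, and
#' hetero-aggregates (one cell of each colour stuck together) are bright
#' in both, appearing double-positive.
#'
#' @param n_single_green,n_single_orange,n_hetero event counts.
#' @param positive_mean,negative_mean log-scale intensity locations of
#'   positive and negative populations.
#' @param cv log-normal spread of each population.
#' @param gate intensity threshold separating positive from negative;
#'   recorded in the `gates` attribute.
#' @param seed optional integer seed.
#' @return data frame with `green` and `orange` intensities, attribute
#'   `gates = c(green, orange)`.
#' @export
make_aggregation_events <- function(n_single_green, n_single_orange,
                                    n_hetero, positive_mean = 5000,
                                    negative_mean = 50, cv = 0.3,
                                    gate = 500, seed = NULL) {
  if (any(c(n_single_green, n_single_orange, n_hetero) < 0)) {
    stop_config("event counts must be >= 0")
  }
  n <- n_single_green + n_single_orange + n_hetero
  gen <- function() {
    rint <- function(n, mu) {
      if (n == 0) return(numeric(0))
      stats::rlnorm(n, log(mu), cv)
    }
    green <- c(rint(n_single_green, positive_mean),
               rint(n_single_orange, negative_mean),
               rint(n_hetero, positive_mean))
    orange <- c(rint(n_single_green, negative_mean),
                rint(n_single_orange, positive_mean),
                rint(n_hetero, positive_mean))
    ord <- sample.int(max(n, 1L), n)
    data.frame(green = green[ord], orange = orange[ord])
  }
  out <- if (is.null(seed)) gen() else with_seed(seed, gen())
  attr(out, "gates") <- c(green = gate, orange = gate)
  out
}
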