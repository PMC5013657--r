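# Bead-calibrated molecule counting and FRET distance calculation.

#' Physical constants for Forster radius calculation
#'
#' @param q_d donor fluorescence quantum yield in the absence of acceptor
#'   (default 0.92, FITC in physiological solution).
#' @param kappa2 dipole orientation factor (default 2/3, freely rotating
#'   isotropically oriented dyes).
#' @param eta refractive index of the medium (default 1.338).
#' @param n_a Avogadro's number, 1/mol.
#' @return object of class `fret_constants`.
#' @export
fret_constants <- function(q_d = 0.92, kappa2 = 2 / 3, eta = 1.338,
                           n_a = 6.02214076e23) {
  if (q_d <= 0 || q_d > 1) stop_config("q_d must lie in (0, 1]")
  if (kappa2 < 0 || kappa2 > 4) stop_config("kappa2 must lie in [0, 4]")
  if (eta <= 1) stop_config("eta must exceed 1")
  structure(list(q_d = q_d, kappa2 = kappa2, eta = eta, n_a = n_a),
            class = "fret_constants")
}

#' Fit a bead calibration curve
#'
#' Ordinary least squares of bead MFI on known antibody-binding capacity
#' (ABC), establishing the linear counts-per-site relation used to convert
#' cell fluorescence to bound-antibody numbers.
#'
#' @param panel data frame with `abc` and `mfi` (see [make_bead_panel()]).
#' @return object of class `bead_calibration`: `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `r_squared` and the underlying `lm` fit.
#' @export
fit_bead_calibration <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("abc", "mfi") %in% names(panel)))
  if (length(unique(panel$abc)) < 2L) {
    stop_config("calibration needs at least 2 distinct ABC levels")
  }
  fit <- stats::lm(mfi ~ abc, data = panel)
  # noise-free panels fit perfectly; summary.lm's warning about it is benign
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- sm$coefficients
  structure(
    list(slope = unname(co["abc", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         slope_se = unname(co["abc", "Std. Error"]),
         intercept_se = unname(co["(Intercept)", "Std. Error"]),
         r_squared = sm$r.squared,
         fit = fit),
    class = "bead_calibration"
  )
}

#' Convert MFI to antibody-binding sites
#'
#' Inverts the bead calibration line: `sites = (mfi - intercept) / slope`,
#' floored at zero.
#'
#' @param mfi measured mean fluorescence intensity (vectorized).
#' @param calibration a [fit_bead_calibration()] result.
#' @return sites per cell.
#' @export
mfi_to_sites <- function(mfi, calibration) {
  stopifnot(inherits(calibration, "bead_calibration"))
  pmax(0, (mfi - calibration$intercept) / calibration$slope)
}

#' Scale whole-cell binding sites to the footprint
#'
#' Divides the sites bound per cell by the cell surface area (smooth
#' sphere, `pi * D^2`) and multiplies by the footprint area.  The sphere
#' model ignores the microvillus excess area and therefore biases the
#' surface low (and the footprint estimate high); this is a documented
#' approximation.
#'
#' @param sites_per_cell antibody-binding sites per cell.
#' @param cell_diameter_um mean cell diameter, um.
#' @param footprint_area_um2 footprint area, um^2.
#' @param surface_area_um2 optional explicit surface area overriding the
#'   sphere model.
#' @return sites within the footprint.
#' @export
footprint_epitope_sites <- function(sites_per_cell, cell_diameter_um,
                                    footprint_area_um2,
                                    surface_area_um2 = NULL) {
  if (is.null(surface_area_um2)) {
    surface_area_um2 <- pi * cell_diameter_um^2
  }
  sites_per_cell * footprint_area_um2 / surface_area_um2
}

#' Molecule count from a fluorescence intensity integral
#'
#' `count = integral / per-molecule intensity`, with first-order error
#' propagation.  The per-molecule intensity must come from a calibration
#' acquired under identical exposure; it is supplied, not derived here.
#'
#' @param integral summed cluster intensity (counts).
#' @param per_molecule intensity per molecule (counts).
#' @param integral_se,per_molecule_se optional standard errors.
#' @return list with `count` and `se`.
#' @export
molecules_from_intensity_integral <- function(integral, per_molecule,
                                              integral_se = 0,
                                              per_molecule_se = 0) {
  if (per_molecule <= 0) stop_config("per_molecule intensity must be positive")
  count <- integral / per_molecule
  rel2 <- (integral_se / max(integral, .Machine$double.eps))^2 +
    (per_molecule_se / per_molecule)^2
  list(count = count, se = abs(count) * sqrt(rel2))
}

#' FRET efficiency from donor quenching
#'
#' `E = 1 - F'_D / F_D`, with `F'_D` and `F_D` the donor intensity in the
#' presence and absence of the acceptor.  A donor gain (`F'_D > F_D`)
#' implies no quenching; the efficiency is clipped to 0 with a warning.
#'
#' @param f_d donor intensity without acceptor.
#' @param f_d_prime donor intensity with acceptor.
#' @return efficiency in [0, 1).
#' @export
fret_efficiency <- function(f_d, f_d_prime) {
  if (f_d <= 0) stop_config("donor intensity f_d must be positive")
  e <- 1 - f_d_prime / f_d
  if (any(e < 0)) {
    warning("donor brighter with acceptor present; efficiency clipped to 0")
    e <- pmax(e, 0)
  }
  e
}

#' Spectral overlap integral of a donor-acceptor pair
#'
#' `J = integral(F_D(lambda) eps_A(lambda) lambda^4 dlambda) /
#' integral(F_D(lambda) dlambda)` by trapezoidal integration on a common
#' wavelength grid (linear interpolation, zero outside each spectrum's
#' support).  Invariant to the donor spectrum's amplitude scale.
#'
#' @param spectra data frame with `wavelength_nm`, `donor_emission`
#'   (arbitrary units) and `acceptor_extinction` (1/(M cm)); or pass the
#'   three vectors separately.
#' @param wavelength_nm,donor_emission,acceptor_extinction alternative
#'   vector interface.
#' @return J in nm^4 / (M cm).
#' @export
overlap_integral <- function(spectra = NULL, wavelength_nm = NULL,
                             donor_emission = NULL,
                             acceptor_extinction = NULL) {
  if (!is.null(spectra)) {
    stopifnot(all(c("wavelength_nm", "donor_emission",
                    "acceptor_extinction") %in% names(spectra)))
    wavelength_nm <- spectra$wavelength_nm
    donor_emission <- spectra$donor_emission
    acceptor_extinction <- spectra$acceptor_extinction
  }
  if (any(donor_emission < 0) || any(acceptor_extinction < 0)) {
    stop_config("spectra must be non-negative")
  }
  ord <- order(wavelength_nm)
  lam <- wavelength_nm[ord]
  fd <- donor_emission[ord]
  ea <- acceptor_extinction[ord]
  denom <- trapz(lam, fd)
  if (denom <= 0) stop_config("donor emission spectrum integrates to zero")
  trapz(lam, fd * ea * lam^4) / denom
}

#' Forster radius from the overlap integral
#'
#' `R0^6 = 9000 ln(10) kappa^2 Q_D J / (128 pi^5 N_A eta^4)` in consistent
#' units; with `J` in nm^4/(M cm) this reduces to the practical form
#' `R0(nm) = 0.02108 * (kappa^2 Q_D eta^-4 J)^(1/6)`.
#'
#' @param j overlap integral in nm^4/(M cm), see [overlap_integral()].
#' @param constants a [fret_constants()].
#' @return Forster radius in nm.
#' @examples
#' forster_radius(2e15)  # ~5.7 nm
#' @export
forster_radius <- function(j, constants = fret_constants()) {
  stopifnot(inherits(constants, "fret_constants"))
  if (any(j < 0)) stop_config("overlap integral must be >= 0")
  0.02108 * (constants$kappa2 * constants$q_d * constants$eta^-4 * j)^(1 / 6)
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts the sixth-power law `E = 1 / (1 + (r/R0)^6)`:
#' `r = R0 * ((1 - E) / E)^(1/6)`.  At `E = 0.5` the distance equals the
#' Forster radius exactly.
#'
#' @param e FRET efficiency, strictly inside (0, 1).
#' @param r0 Forster radius, nm.
#' @return distance in nm.
#' @export
fret_distance <- function(e, r0) {
  if (any(e <= 0)) {
    stop_config("E <= 0: no transfer detected, distance unbounded")
  }
  if (any(e >= 1)) {
    stop_config("E >= 1: complete transfer, distance indistinguishable from 0")
  }
  r0 * ((1 - e) / e)^(1 / 6)
}

#' Quench/gain statistics of a FRET time series
#'
#' Baseline is the mean intensity before the addition; the response is the
#' mean inside a saturation window after the addition (default 2-3 min).
#' Reports the donor decrease and acceptor increase with propagated
#' standard errors, and the implied efficiency `E = decrease / baseline`.
#'
#' @param series data frame with `time_s`, `donor`, `acceptor` (see
#'   [make_fret_series()]).
#' @param addition_time_s time the second reagent was added, s.
#' @param window_s response window relative to the addition, s (default
#'   `c(120, 180)`).
#' @return list with per-trace baseline/response/change/SE and
#'   `efficiency`.
#' @export
quench_gain_stats <- function(series, addition_time_s,
                              window_s = c(120, 180)) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "donor", "acceptor") %in% names(series)))
  pre <- series$time_s < addition_time_s
  win <- series$time_s >= addition_time_s + window_s[1] &
    series$time_s <= addition_time_s + window_s[2]
  if (!any(pre) || !any(win)) {
    stop_config("series does not cover the baseline and response windows")
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  one <- function(x) {
    b <- mean(x[pre]); r <- mean(x[win])
    list(baseline = b, response = r,
         change_se = sqrt(se(x[pre])^2 + se(x[win])^2))
  }
  d <- one(series$donor)
  a <- one(series$acceptor)
  list(donor_baseline = d$baseline, donor_response = d$response,
       donor_decrease = d$baseline - d$response,
       donor_decrease_se = d$change_se,
       acceptor_baseline = a$baseline, acceptor_response = a$response,
       acceptor_increase = a$response - a$baseline,
       acceptor_increase_se = a$change_se,
       efficiency = (d$baseline - d$response) / d$baseline)
}

#' Hetero-aggregate fraction from a two-colour event table
#'
#' Fraction of events positive in both colour channels (a green-labelled
#' cell aggregated with an orange-labelled cell), as a percentage of all
#' events.
#'
#' @param events data frame with `green` and `orange` intensity columns.
#' @param gates named numeric vector `c(green = ..., orange = ...)` of
#'   positivity thresholds; defaults to the table's `gates` attribute.
#' @return percentage of double-positive events.
#' @export
heteroaggregate_fraction <- function(events, gates = attr(events, "gates")) {
  stopifnot(is.data.frame(events),
            all(c("green", "orange") %in% names(events)))
  if (nrow(events) == 0L) {
    stop_config("no events: aggregate fraction undefined")
  }
  if (is.null(gates)) stop_config("gates must be supplied")
  dp <- events$green > gates[["green"]] & events$orange > gates[["orange"]]
  100 * sum(dp) / nrow(events)
}
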