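#' Optical configuration for TIRF height mapping
#'
#' Bundles the illumination geometry that sets the evanescent-field
#' penetration depth: excitation wavelengths per channel, the incidence
#' angle, and the refractive indices of the coverslip and the medium.
#' Total internal reflection requires `n_glass * sin(theta) > n_medium`.
#'
#' @param wavelengths_nm named numeric vector of excitation wavelengths in
#'   nm.  Defaults to the three-laser layout used for triple-colour
#'   footprinting: 488 nm (headpiece reporter), 561 nm (extension
#'   reporter), 641 nm (membrane dye).
#' @param theta_deg TIRF incidence angle in degrees (default 70).
#' @param n_glass refractive index of the coverslip/immersion side
#'   (default 1.515).
#' @param n_medium refractive index of the aqueous medium (default 1.338).
#' @param objective_na numerical aperture, carried as metadata only.
#' @param pixel_size_nm camera pixel size in the sample plane, nm.
#' @return an object of class `optical_config`.
#' @examples
#' opt <- optical_config()
#' penetration_depth(opt, "membrane")
#' @export
optical_config <- function(wavelengths_nm = c(mab24 = 488, kim127 = 561,
                                              membrane = 641),
                           theta_deg = 70,
                           n_glass = 1.515,
                           n_medium = 1.338,
                           objective_na = 1.45,
                           pixel_size_nm = 64) {
  if (any(wavelengths_nm <= 0)) stop_config("wavelengths must be positive")
  if (is.null(names(wavelengths_nm))) {
    names(wavelengths_nm) <- paste0("ch", seq_along(wavelengths_nm))
  }
  if (n_glass * sin(theta_deg * pi / 180) <= n_medium) {
    stop_config(paste(
      "incidence angle is at or below the critical angle:",
      "n_glass*sin(theta) must exceed n_medium for total internal reflection"
    ))
  }
  if (pixel_size_nm <= 0) stop_config("pixel_size_nm must be positive")
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      theta_deg = theta_deg,
      n_glass = n_glass,
      n_medium = n_medium,
      objective_na = objective_na,
      pixel_size_nm = pixel_size_nm
    ),
    class = "optical_config"
  )
}

#' Evanescent-field penetration depth
#'
#' Depth constant of the exponentially decaying evanescent intensity,
#' `d = lambda / (4 * pi * sqrt(n1^2 sin^2(theta) - n2^2))`.  The depth is
#' linear in wavelength and diverges as the incidence angle approaches the
#' critical angle.
#'
#' @param optics an [optical_config()].
#' @param channel channel name or index into `optics$wavelengths_nm`, or a
#'   numeric wavelength in nm.
#' @return penetration depth in nm.
#' @examples
#' penetration_depth(optical_config(), 488)  # ~79.9 nm
#' @export
penetration_depth <- function(optics, channel = "membrane") {
  stopifnot(inherits(optics, "optical_config"))
  lambda <- if (is.numeric(channel) && channel > 100) {
    channel
  } else {
    lam <- optics$wavelengths_nm[channel]
    if (any(is.na(lam))) stop_config("unknown channel '%s'", channel)
    unname(lam)
  }
  disc <- (optics$n_glass * sin(optics$theta_deg * pi / 180))^2 -
    optics$n_medium^2
  if (disc <= 0) {
    stop_config("no evanescent field: at or below the critical angle")
  }
  lambda / (4 * pi * sqrt(disc))
}
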