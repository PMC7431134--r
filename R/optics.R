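#' Optical configuration of a transmission polarized-light acquisition
#'
#' Bundles the optical parameters needed by the instrument-matrix model and
#' the weak-object transfer functions: wavelength, detection and illumination
#' numerical apertures, object-space pixel size, z-step, and the compensatory
#' retardance chi of the liquid-crystal universal polarizer that sets the
#' ellipticity of the four elliptical illumination states.
#'
#' @param wavelength Illumination wavelength in micrometres.
#' @param na_detection Detection-side numerical aperture (dimensionless).
#' @param na_illumination Illumination (condenser) numerical aperture. Must not
#'   exceed `na_detection`.
#' @param pixel_size Object-space lateral pixel size in micrometres.
#' @param z_step Axial step between planes of a z-stack, micrometres.
#' @param chi Compensatory retardance of the LC polarizer, radians, in the
#'   open interval (0, pi). Defaults to 0.06*pi (about 3% of a wave), a
#'   typical swing for LC universal polarizers.
#' @param medium_index Refractive index of the imaging medium (default 1,
#'   air-path modelling). NAs must be strictly below this.
#' @return An object of class `optics_config`.
#' @examples
#' opt <- optics_config(wavelength = 0.532, na_detection = 0.55,
#'                      na_illumination = 0.4, pixel_size = 0.2, z_step = 0.5)
#' opt$chi
#' @export
optics_config <- function(wavelength, na_detection, na_illumination,
                          pixel_size, z_step, chi = 0.06 * pi,
                          medium_index = 1.0) {
  stopifnot(is.numeric(wavelength), is.numeric(na_detection),
            is.numeric(na_illumination), is.numeric(pixel_size),
            is.numeric(z_step), is.numeric(chi))
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("wavelength must be a positive finite length (micrometres)")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive finite length (micrometres)")
  if (!is.finite(z_step) || z_step <= 0)
    stop("z_step must be a positive finite length (micrometres)")
  if (!(na_illumination > 0 && na_illumination <= na_detection &&
        na_detection < medium_index))
    stop("require 0 < na_illumination <= na_detection < medium_index")
  if (!is.finite(chi) || chi <= 0 || chi >= pi)
    stop("chi must lie in the open interval (0, pi): ",
         "the instrument matrix is degenerate at the endpoints")
  structure(list(wavelength = wavelength,
                 na_detection = na_detection,
                 na_illumination = na_illumination,
                 pixel_size = pixel_size,
                 z_step = z_step,
                 chi = chi,
                 medium_index = medium_index),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("optics_config:\n")
  cat(sprintf("  wavelength      %.4g um\n", x$wavelength))
  cat(sprintf("  NA det / illum  %.3g / %.3g (sigma = %.3g)\n",
              x$na_detection, x$na_illumination,
              x$na_illumination / x$na_detection))
  cat(sprintf("  pixel / z-step  %.4g / %.4g um\n", x$pixel_size, x$z_step))
  cat(sprintf("  LC swing chi    %.4g rad (%.3g waves)\n",
              x$chi, x$chi / (2 * pi)))
  invisible(x)
}
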