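#' Camera and optics description of an SMLM experiment
#'
#' Bundles the camera calibration (bias offset, effective electronic gain) and
#' the optical constants (emission wavelength, numerical aperture,
#' magnification, physical pixel size) that every analysis stage depends on.
#' These are the only experiment-specific inputs the pipeline needs.
#'
#' @param offset ADU bias offset of the camera (counts added to every pixel).
#' @param gain Effective electronic gain in ADU per photoelectron. For an
#'   EMCCD this is the single effective value including the EM register.
#' @param pixel_size_nm Physical size of one camera pixel in nm.
#' @param magnification Total magnification of the imaging system.
#' @param na Numerical aperture of the objective.
#' @param wavelength_nm Emission maximum of the fluorophore in nm.
#'
#' @return An object of class `camera_optics`.
#' @seealso [derive_optics()], [to_photoelectrons()], [standard_camera()]
#' @export
#' @examples
#' cam <- camera_optics(offset = 100, gain = 2, pixel_size_nm = 16000,
#'                      magnification = 16000 / 70, na = 1.49,
#'                      wavelength_nm = 670)
#' pixel_eff_nm(cam)  # 70 nm in the sample plane
camera_optics <- function(offset, gain, pixel_size_nm, magnification, na,
                          wavelength_nm) {
  for (nm in c("offset", "gain", "pixel_size_nm", "magnification", "na",
               "wavelength_nm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (gain <= 0) stop("'gain' must be > 0", call. = FALSE)
  if (pixel_size_nm <= 0) stop("'pixel_size_nm' must be > 0", call. = FALSE)
  if (magnification <= 0) stop("'magnification' must be > 0", call. = FALSE)
  if (na <= 0) stop("'na' must be > 0", call. = FALSE)
  if (wavelength_nm <= 0) stop("'wavelength_nm' must be > 0", call. = FALSE)
  structure(
    list(offset = offset, gain = gain, pixel_size_nm = pixel_size_nm,
         magnification = magnification, na = na,
         wavelength_nm = wavelength_nm),
    class = "camera_optics"
  )
}

#' @export
print.camera_optics <- function(x, ...) {
  cat("<camera_optics>\n")
  cat(sprintf("  offset %g ADU, gain %g ADU/e-\n", x$offset, x$gain))
  cat(sprintf("  pixel %g nm, magnification %.4g (p_eff %.4g nm)\n",
              x$pixel_size_nm, x$magnification, pixel_eff_nm(x)))
  cat(sprintf("  NA %g, wavelength %g nm\n", x$na, x$wavelength_nm))
  invisible(x)
}

#' Effective sample-plane pixel size
#'
#' @param cam A [camera_optics()] object.
#' @return Effective pixel size in nm per pixel (physical pixel size divided
#'   by magnification).
#' @export
pixel_eff_nm <- function(cam) {
  stopifnot(inherits(cam, "camera_optics"))
  cam$pixel_size_nm / cam$magnification
}

#' Derive pixel-domain optical constants
#'
#' Computes the quantities the per-frame analysis works with: the Airy disk
#' radius in camera pixels, `r_airy_px = 0.61 * lambda * M / (NA * mu)`; the
#' theoretical Gaussian PSF width `s0_px = 0.21 * lambda * M / (NA * mu)`;
#' and the half-window `h_f = ceiling(r_airy_px)` used for smoothing and for
#' the square fit region. The 0.61 prefactor is the first minimum of the Airy
#' pattern; 0.21 is the standard least-squares Gaussian approximation of the
#' in-focus PSF.
#'
#' @param cam A [camera_optics()] object.
#' @return An object of class `optics_derived` with fields `r_airy_px`,
#'   `s0_px`, `h_f` and `p_eff_nm`.
#' @export
#' @examples
#' opt <- derive_optics(standard_camera())
#' opt$r_airy_px  # ~3.92 px at 70 nm/pixel, NA 1.49, 670 nm
derive_optics <- function(cam) {
  stopifnot(inherits(cam, "camera_optics"))
  p_eff <- pixel_eff_nm(cam)
  r_airy <- 0.61 * cam$wavelength_nm / (cam$na * p_eff)
  if (r_airy < 1)
    stop("Airy disk radius is below one pixel (", signif(r_airy, 4),
         " px): the PSF is undersampled for this camera/optics combination",
         call. = FALSE)
  s0 <- 0.21 * cam$wavelength_nm / (cam$na * p_eff)
  structure(
    list(r_airy_px = r_airy, s0_px = s0, h_f = as.integer(ceiling(r_airy)),
         p_eff_nm = p_eff),
    class = "optics_derived"
  )
}

#' @export
print.optics_derived <- function(x, ...) {
  cat(sprintf("<optics_derived> r_airy %.4g px, s0 %.4g px, h_f %d, p_eff %.4g nm\n",
              x$r_airy_px, x$s0_px, x$h_f, x$p_eff_nm))
  invisible(x)
}

#' Full width at half maximum of the PSF in nm
#'
#' `2 * sqrt(2 * log(2)) * s0`, converted to nm. This is the default
#' tolerance radius for localization matching in [match_localizations()].
#'
#' @param cam A [camera_optics()] object.
#' @return FWHM in nm.
#' @export
psf_fwhm_nm <- function(cam) {
  opt <- derive_optics(cam)
  2 * sqrt(2 * log(2)) * opt$s0_px * opt$p_eff_nm
}

#' Convert a raw camera frame to photoelectron counts
#'
#' Applies the camera model `n(i, j) = (I(i, j) - offset) / gain`. Values
#' below the offset come out negative and are kept (not clipped) so that the
#' subsequent background fit is unbiased.
#'
#' @param frame Numeric or integer matrix of raw ADU pixel values.
#' @param cam A [camera_optics()] object.
#' @return A numeric matrix of the same shape in photoelectron units.
#' @export
to_photoelectrons <- function(frame, cam) {
  stopifnot(inherits(cam, "camera_optics"))
  if (!is.matrix(frame) || length(frame) == 0L)
    stop("'frame' must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(frame)))
    stop("'frame' contains non-finite pixel values", call. = FALSE)
  (frame - cam$offset) / cam$gain
}

#' Canonical EMCCD/TIRF camera used throughout the documentation and tests
#'
#' A 16 um pixel EMCCD behind a high-NA TIRF objective with post-magnification
#' giving an effective sample-plane pixel of exactly 70 nm; far-red emission
#' (670 nm, e.g. Alexa Fluor 647), NA 1.49, bias offset 100 ADU, effective
#' gain 2 ADU per photoelectron.
#'
#' @return A [camera_optics()] object.
#' @export
standard_camera <- function() {
  camera_optics(offset = 100, gain = 2, pixel_size_nm = 16000,
                magnification = 16000 / 70, na = 1.49, wavelength_nm = 670)
}
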