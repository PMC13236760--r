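#' TIRF optical model
#'
#' Bundles the optical parameters needed to convert measured spot widths
#' into physical sphere diameters: the evanescent-field penetration depth
#' \eqn{d} (the height at which excitation intensity has fallen to 1/e of
#' its value at the glass interface), the derived half-intensity height
#' \eqn{z_{1/2} = d \ln 2}, the effective lateral PSF FWHM per imaging
#' channel, and the camera pixel size.
#'
#' The half-intensity height is carried unrounded (69.31 nm for the
#' default d = 100 nm) in all computations; display rounding is left to
#' the caller.
#'
#' @param penetration_depth_nm evanescent decay constant d, in nm.
#' @param psf_fwhm_nm named numeric vector of effective lateral PSF FWHM
#'   per channel, in nm. May be `NULL` before bead calibration.
#' @param pixel_size_nm camera pixel size, in nm.
#' @return An object of class `optical_model`.
#' @examples
#' om <- optical_model()
#' om$half_height_nm  # 100 * log(2)
#' @export
optical_model <- function(penetration_depth_nm = 100,
                          psf_fwhm_nm = c(red = 289, green = 312),
                          pixel_size_nm = 46) {
  stopifnot(is.numeric(penetration_depth_nm), length(penetration_depth_nm) == 1)
  if (penetration_depth_nm <= 0) stop("penetration depth must be > 0")
  if (pixel_size_nm <= 0) stop("pixel size must be > 0")
  if (!is.null(psf_fwhm_nm) && any(psf_fwhm_nm <= 0))
    stop("PSF FWHM must be > 0")
  structure(
    list(
      penetration_depth_nm = penetration_depth_nm,
      half_height_nm = penetration_depth_nm * log(2),
      psf_fwhm_nm = psf_fwhm_nm,
      pixel_size_nm = pixel_size_nm
    ),
    class = "optical_model"
  )
}

#' @export
print.optical_model <- function(x, ...) {
  cat("TIRF optical model\n")
  cat(sprintf("  penetration depth d : %.1f nm\n", x$penetration_depth_nm))
  cat(sprintf("  half-intensity z1/2 : %.1f nm\n", x$half_height_nm))
  if (!is.null(x$psf_fwhm_nm)) {
    nm <- names(x$psf_fwhm_nm)
    if (is.null(nm)) nm <- seq_along(x$psf_fwhm_nm)
    for (i in seq_along(x$psf_fwhm_nm))
      cat(sprintf("  PSF FWHM [%s]      : %.1f nm\n", nm[i], x$psf_fwhm_nm[i]))
  }
  cat(sprintf("  pixel size          : %.1f nm\n", x$pixel_size_nm))
  invisible(x)
}

# resolve a channel's PSF FWHM from a model, a named vector, or a scalar
.psf_of <- function(model, channel = NULL) {
  psf <- model$psf_fwhm_nm
  if (is.null(psf)) stop("optical model carries no PSF; calibrate first")
  if (length(psf) == 1) return(unname(psf))
  if (is.null(channel)) return(unname(psf[1]))
  if (!channel %in% names(psf)) stop("unknown channel: ", channel)
  unname(psf[channel])
}

#' Evanescent excitation intensity at height z
#'
#' Relative excitation intensity of the evanescent field at height `z_nm`
#' above the glass interface, `exp(-z/d)`; equals 1 at the interface and
#' decays to 1/e at one penetration depth.
#'
#' @param z_nm height above the interface, nm (vectorized, must be >= 0).
#' @param model an [optical_model()].
#' @return relative intensity in \[0, 1\].
#' @export
evanescent_intensity <- function(z_nm, model = optical_model()) {
  if (any(z_nm < 0)) stop("height z must be >= 0")
  exp(-z_nm / model$penetration_depth_nm)
}

#' Half-intensity height of the evanescent field
#'
#' Height at which the excitation intensity falls to half of its interface
#' value: \eqn{z_{1/2} = d \ln 2} (about 69 nm for d = 100 nm).
#'
#' @inheritParams evanescent_intensity
#' @return height in nm.
#' @export
half_intensity_height <- function(model = optical_model()) {
  model$half_height_nm
}

#' Intrinsic footprint of a sphere in the evanescent field
#'
#' For a fluorescent sphere of diameter `D` resting on the glass, emission
#' falls to half of its maximum at the contour where the sphere crosses
#' the half-intensity height z1/2. The diameter of that contour — the
#' width that would be measured with perfect optics — is
#' \eqn{2\sqrt{D z_{1/2} - z_{1/2}^2}}.
#'
#' @param diameter_nm sphere diameter D, nm (vectorized).
#' @param z_half_nm half-intensity height z1/2, nm.
#' @return intrinsic FWHM, nm.
#' @export
intrinsic_sphere_footprint <- function(diameter_nm,
                                       z_half_nm = 100 * log(2)) {
  if (z_half_nm <= 0) stop("z1/2 must be > 0")
  if (any(diameter_nm < z_half_nm))
    stop("sphere diameter below z1/2: half-intensity contour undefined")
  2 * sqrt(diameter_nm * z_half_nm - z_half_nm^2)
}

#' Quadrature deblurring of a measured width
#'
#' Removes a blur contribution from a measured FWHM assuming the widths
#' add approximately in quadrature:
#' \eqn{\sqrt{\mathrm{meas}^2 - \mathrm{blur}^2}}. Never enlarges.
#'
#' @param fwhm_measured_nm measured FWHM, nm (vectorized).
#' @param fwhm_blur_nm blur FWHM to remove, nm.
#' @return deblurred FWHM, nm.
#' @export
quadrature_deblur <- function(fwhm_measured_nm, fwhm_blur_nm) {
  if (any(fwhm_blur_nm < 0)) stop("blur FWHM must be >= 0")
  if (any(fwhm_measured_nm < fwhm_blur_nm))
    stop("measured FWHM below blur width: object below the resolution floor")
  sqrt(fwhm_measured_nm^2 - fwhm_blur_nm^2)
}

#' Effective lateral PSF from calibration beads
#'
#' Estimates the effective lateral PSF FWHM of the whole imaging pipeline
#' from the measured width of sub-resolution calibration beads of known
#' diameter: the bead's intrinsic footprint in the evanescent field is
#' computed, then removed from the measured width in quadrature.
#'
#' @param fwhm_bead_measured_nm measured bead FWHM, nm.
#' @param bead_diameter_nm known bead diameter, nm (110 for TetraSpeck).
#' @param z_half_nm half-intensity height, nm.
#' @return effective PSF FWHM, nm.
#' @examples
#' psf_from_beads(308, 110, 100 * log(2))  # about 289 nm
#' @export
psf_from_beads <- function(fwhm_bead_measured_nm, bead_diameter_nm = 110,
                           z_half_nm = 100 * log(2)) {
  intr <- intrinsic_sphere_footprint(bead_diameter_nm, z_half_nm)
  quadrature_deblur(fwhm_bead_measured_nm, intr)
}

#' Sphere diameter from a deblurred footprint
#'
#' Algebraic inverse of [intrinsic_sphere_footprint()]: converts a
#' PSF-deblurred footprint FWHM into the physical diameter of a sphere
#' resting on the glass,
#' \eqn{D = ((\mathrm{FWHM}/2)^2 + z_{1/2}^2) / z_{1/2}}.
#'
#' @param fwhm_deblurred_nm deblurred footprint FWHM, nm (vectorized).
#' @param z_half_nm half-intensity height, nm.
#' @return physical diameter, nm (always >= z1/2).
#' @export
footprint_to_diameter <- function(fwhm_deblurred_nm,
                                  z_half_nm = 100 * log(2)) {
  if (z_half_nm <= 0) stop("z1/2 must be > 0")
  if (any(fwhm_deblurred_nm < 0)) stop("FWHM must be >= 0")
  ((fwhm_deblurred_nm / 2)^2 + z_half_nm^2) / z_half_nm
}

#' Physical diameter from a measured spot width
#'
#' The full inversion chain: the channel PSF is removed from the measured
#' spot FWHM in quadrature, and the resulting intrinsic footprint is
#' converted to the physical diameter of a sphere sitting on the glass.
#' Strictly increasing in the measured FWHM at fixed PSF.
#'
#' @param fwhm_spot_measured_nm measured spot FWHM, nm (vectorized).
#' @param psf_fwhm_nm effective lateral PSF FWHM, nm. Defaults to the
#'   model's PSF for `channel`.
#' @param model an [optical_model()].
#' @param channel channel name used to look up the PSF in `model` when
#'   `psf_fwhm_nm` is not given.
#' @return physical diameter, nm.
#' @examples
#' om <- optical_model()
#' diameter_from_measurements(350, 289, om)  # about 210 nm
#' diameter_from_measurements(350, 312, om)  # about 160 nm
#' @export
diameter_from_measurements <- function(fwhm_spot_measured_nm,
                                       psf_fwhm_nm = NULL,
                                       model = optical_model(),
                                       channel = NULL) {
  if (is.null(psf_fwhm_nm)) psf_fwhm_nm <- .psf_of(model, channel)
  deb <- quadrature_deblur(fwhm_spot_measured_nm, psf_fwhm_nm)
  footprint_to_diameter(deb, model$half_height_nm)
}
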