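#' H&E-like rendering palette
#'
#' RGB triples (on a 0-1 scale) emulating the appearance of a
#' hematoxylin-and-eosin stained smear: blue-violet nuclei, pink
#' cytoplasm, near-white background. Only the visual palette is
#' modelled; stain chemistry is out of scope.
#'
#' @return named list with `background`, `cytoplasm` and `nucleus`
#'   RGB triples in `[0, 1]`.
#' @export
he_palette <- function() {
  list(
    background = c(245, 242, 245) / 255,
    cytoplasm  = c(230, 150, 180) / 255,
    nucleus    = c(64, 32, 128) / 255
  )
}

#' Optics model of the tablet microscope
#'
#' Describes the virtual instrument's imaging path: a 20X/0.4NA
#' objective (chosen in the field to maximise field of view while
#' retaining diagnostic resolution), a square sensor crop, and a
#' simple incoherent defocus model. Out-of-focus blur is a Gaussian
#' point-spread function whose sigma grows linearly with defocus
#' beyond half the depth of field:
#' `sigma(dz) = max(0, k * (|dz| - depth_of_field / 2))` micrometres.
#'
#' @param magnification objective magnification (metadata only).
#' @param numerical_aperture objective NA.
#' @param pixel_pitch micrometres per pixel at the sample plane.
#' @param field_shape integer `c(H, W)` field size in pixels.
#' @param depth_of_field micrometres; default `wavelength / NA^2`.
#' @param blur_coefficient `k`, PSF sigma growth in micrometres of sigma
#'   per micrometre of defocus beyond the depth of field.
#' @param noise_sigma additive Gaussian intensity noise (0-1 scale) applied
#'   per channel before 8-bit quantisation.
#' @param wavelength illumination wavelength in micrometres (used only for
#'   the depth-of-field default).
#' @param palette rendering palette, see [he_palette()].
#' @return an object of class `optics_model`.
#' @export
optics_model <- function(magnification = 20,
                         numerical_aperture = 0.4,
                         pixel_pitch = 0.5,
                         field_shape = c(512L, 512L),
                         depth_of_field = NULL,
                         blur_coefficient = 0.2,
                         noise_sigma = 2 / 255,
                         wavelength = 0.55,
                         palette = he_palette()) {
  if (is.null(depth_of_field)) {
    depth_of_field <- wavelength / numerical_aperture^2
  }
  scalars <- c(magnification = magnification,
               numerical_aperture = numerical_aperture,
               pixel_pitch = pixel_pitch,
               depth_of_field = depth_of_field,
               blur_coefficient = blur_coefficient,
               wavelength = wavelength)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    stopf("all optics scalars must be positive and finite")
  }
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  field_shape <- as.integer(field_shape)
  if (length(field_shape) != 2 || any(field_shape < 3)) {
    stopf("field_shape must be two integers >= 3")
  }
  structure(
    list(magnification = magnification,
         numerical_aperture = numerical_aperture,
         pixel_pitch = pixel_pitch,
         field_shape = field_shape,
         depth_of_field = depth_of_field,
         blur_coefficient = blur_coefficient,
         noise_sigma = noise_sigma,
         wavelength = wavelength,
         palette = palette),
    class = "optics_model"
  )
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf("<optics_model> %gX/%.2gNA, %dx%d px @ %g um/px, DOF %.3g um, k %.3g, noise %.4g\n",
              x$magnification, x$numerical_aperture,
              x$field_shape[1], x$field_shape[2], x$pixel_pitch,
              x$depth_of_field, x$blur_coefficient, x$noise_sigma))
  invisible(x)
}

#' Defocus PSF sigma
#'
#' Gaussian PSF sigma (micrometres) at a given defocus. Zero inside the
#' depth of field, then linear growth.
#'
#' @param optics an [optics_model()].
#' @param dz defocus `z - z*(x, y)` in micrometres (vectorised).
#' @return sigma in micrometres, `>= 0`.
#' @export
psf_sigma <- function(optics, dz) {
  pmax(0, optics$blur_coefficient * (abs(dz) - optics$depth_of_field / 2))
}

# Physical field of view c(width, height) in micrometres.
field_of_view <- function(optics) {
  c(optics$field_shape[2], optics$field_shape[1]) * optics$pixel_pitch
}

# Gaussian blur of a matrix by frequency-domain multiplication with the
# analytic Gaussian transfer function exp(-2 pi^2 sigma^2 |f|^2).
# Periodic boundary conditions; adequate for fields whose borders are
# background. sigma_px in pixels.
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  h <- nrow(mat)
  w <- ncol(mat)
  fy <- c(0:floor(h / 2), if (h > 1) -(ceiling(h / 2) - 1):-1) / h
  fx <- c(0:floor(w / 2), if (w > 1) -(ceiling(w / 2) - 1):-1) / w
  transfer <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, "+"))
  Re(stats::fft(stats::fft(mat) * transfer, inverse = TRUE)) / (h * w)
}
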