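# Synthetic CT-like phantom: one ellipsoidal lesion in a textured background.
#
# The phantom stands in for contrast-enhanced CT of a liver lesion: an
# enhancing ellipsoid on a darker background, with spatially correlated
# Gaussian texture so that gray-level matrices are non-trivial at a fixed
# bin width of 25 intensity units.

#' Parameters of the synthetic phantom
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Voxel spacing in mm (default the CT grid 0.97 x 0.97 x 3.0).
#' @param lesion_radius_mm Per-axis ellipsoid semi-axes in mm.
#' @param lesion_mean_intensity,background_mean_intensity Mean intensities
#'   (HU-like units) inside and outside the lesion.
#' @param texture_correlation_length_mm Correlation length of the Gaussian
#'   texture field in mm; 0 gives white noise.
#' @param noise_sd Standard deviation of the texture field (same units as the
#'   intensities); 0 gives a noiseless piecewise-constant image.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           spacing = c(0.97, 0.97, 3.0),
                           lesion_radius_mm = c(12, 12, 12),
                           lesion_mean_intensity = 120,
                           background_mean_intensity = 80,
                           texture_correlation_length_mm = 4,
                           noise_sd = 15) {
  p <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
            lesion_radius_mm = as.numeric(lesion_radius_mm),
            lesion_mean_intensity = lesion_mean_intensity,
            background_mean_intensity = background_mean_intensity,
            texture_correlation_length_mm = texture_correlation_length_mm,
            noise_sd = noise_sd)
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 2L))
    stop("grid_shape must be 3 integers >= 2")
  if (length(p$spacing) != 3L || any(p$spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (length(p$lesion_radius_mm) != 3L || any(p$lesion_radius_mm <= 0))
    stop("lesion_radius_mm must be 3 strictly positive semi-axes")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$texture_correlation_length_mm < 0)
    stop("texture_correlation_length_mm must be >= 0")
  extent <- (p$grid_shape - 1) * p$spacing
  ax <- c("x", "y", "z")
  for (a in 1:3) {
    if (2 * p$lesion_radius_mm[a] >= extent[a])
      stop(sprintf(
        "lesion exceeds grid on axis %s: semi-axis %.2f mm vs half-extent %.2f mm",
        ax[a], p$lesion_radius_mm[a], extent[a] / 2))
  }
  invisible(TRUE)
}

# Zero-mean, unit-variance Gaussian random field with approximately Gaussian
# correlation of length `corr_mm` (circular convolution via FFT).
gaussian_random_field <- function(dims, spacing, corr_mm) {
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  if (corr_mm <= 0) return(w)
  kern1d <- function(n, sp) {
    sigma <- corr_mm / sp
    pos <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # wrapped coordinates
    k <- exp(-pos^2 / (2 * sigma^2))
    k
  }
  kx <- kern1d(dims[1], spacing[1])
  ky <- kern1d(dims[2], spacing[2])
  kz <- kern1d(dims[3], spacing[3])
  k <- outer(outer(kx, ky), kz)
  dim(k) <- dims
  k <- k / sqrt(sum(k^2))  # unit-variance output field
  g <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    prod(dims)
  g
}

#' Generate a phantom image and its ground-truth lesion mask
#'
#' The image is `background_mean_intensity` outside and
#' `lesion_mean_intensity` inside an ellipsoid centred on the grid, plus
#' `noise_sd` times a unit-variance correlated Gaussian texture field.
#' Identical seeds give bit-identical output.
#'
#' @param params A [phantom_params()] list.
#' @param seed Integer RNG seed.
#' @param center_mm Optional lesion centre (mm); defaults to the grid centre.
#' @return List with elements `image` ([image_volume()]) and `mask`
#'   (ground-truth lesion [roi_mask()]).
#' @export
generate_phantom <- function(params, seed, center_mm = NULL) {
  validate_phantom_params(params)
  d <- params$grid_shape
  sp <- params$spacing
  if (is.null(center_mm)) center_mm <- (d - 1) * sp / 2
  # lesion must fit strictly inside the grid around its centre
  extent_hi <- (d - 1) * sp
  ax <- c("x", "y", "z")
  for (a in 1:3) {
    if (center_mm[a] - params$lesion_radius_mm[a] <= 0 ||
        center_mm[a] + params$lesion_radius_mm[a] >= extent_hi[a])
      stop(sprintf("lesion exceeds grid on axis %s", ax[a]))
  }
  cx <- (seq_len(d[1]) - 1) * sp[1] - center_mm[1]
  cy <- (seq_len(d[2]) - 1) * sp[2] - center_mm[2]
  cz <- (seq_len(d[3]) - 1) * sp[3] - center_mm[3]
  r <- params$lesion_radius_mm
  m2 <- outer(outer((cx / r[1])^2, (cy / r[2])^2, `+`), (cz / r[3])^2, `+`)
  mask <- array(as.integer(m2 <= 1), dim = d)
  img <- array(params$background_mean_intensity, dim = d)
  img[mask == 1L] <- params$lesion_mean_intensity
  if (params$noise_sd > 0) {
    g <- with_seed(seed, gaussian_random_field(
      d, sp, params$texture_correlation_length_mm))
    img <- img + params$noise_sd * g
  }
  list(image = image_volume(img, sp), mask = roi_mask(mask, sp))
}
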