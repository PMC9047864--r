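# Shared fixtures: small deterministic phantoms used by unit tests and by the
# frozen cross-implementation oracle values (tools/oracle/). The oracle
# freeze script regenerates exactly these cases, so their definitions must
# stay in sync with oracle-feature-values.csv.

oracle_phantom_case <- function(i) {
  spec <- list(
    list(grid = c(16L, 16L, 12L), sp = c(1, 1, 1), r = c(5, 4, 4),
         noise = 20, corr = 0, seed = 101L, perturb = FALSE),
    list(grid = c(16L, 16L, 12L), sp = c(0.97, 0.97, 3.0), r = c(6, 5, 8),
         noise = 15, corr = 2, seed = 102L, perturb = FALSE),
    list(grid = c(18L, 18L, 10L), sp = c(1.2, 0.8, 2.5), r = c(7, 5, 7),
         noise = 25, corr = 3, seed = 103L, perturb = TRUE),
    list(grid = c(14L, 14L, 14L), sp = c(1, 1, 1), r = c(5, 5, 5),
         noise = 30, corr = 1, seed = 104L, perturb = TRUE),
    list(grid = c(16L, 16L, 16L), sp = c(0.97, 0.97, 3.0), r = c(6, 6, 10),
         noise = 10, corr = 4, seed = 105L, perturb = FALSE))[[i]]
  p <- phantom_params(grid_shape = spec$grid, spacing = spec$sp,
                      lesion_radius_mm = spec$r, noise_sd = spec$noise,
                      texture_correlation_length_mm = spec$corr)
  ph <- generate_phantom(p, spec$seed)
  mask <- ph$mask
  if (spec$perturb) {
    mask <- simulate_delineation(
      ph$mask, profile = observer_profile("CECT", 0.8, 1.2),
      observer = 1L, session = 1L, seed = spec$seed + 7L)
  }
  list(image = ph$image, mask = mask)
}

# A tiny image/mask pair from explicit voxel values (single-slice by default).
tiny_roi <- function(values, dims = c(length(values), 1L, 1L),
                     spacing = c(1, 1, 1)) {
  img <- image_volume(array(as.numeric(values), dims), spacing)
  msk <- roi_mask(array(1L, dims), spacing)
  list(image = img, mask = msk,
       disc = discretize_fixed_bin_width(img, msk, 25))
}
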