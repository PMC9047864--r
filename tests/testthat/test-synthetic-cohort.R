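# Phantom generation and simulated multi-observer delineation.

small_phantom <- function(noise_sd = 15, corr = 3, seed = 7) {
  p <- phantom_params(grid_shape = c(32, 32, 24),
                      lesion_radius_mm = c(8, 8, 8),
                      noise_sd = noise_sd,
                      texture_correlation_length_mm = corr,
                      spacing = c(1, 1, 1.5))
  generate_phantom(p, seed)
}

test_that("noise-free phantom is exactly piecewise constant", {
  p <- phantom_params(grid_shape = c(24, 24, 16), lesion_radius_mm = c(6, 6, 6),
                      noise_sd = 0)
  ph <- generate_phantom(p, 1)
  expect_true(all(ph$image$data[ph$mask$data == 1L] ==
                    p$lesion_mean_intensity))
  expect_true(all(ph$image$data[ph$mask$data == 0L] ==
                    p$background_mean_intensity))
})

test_that("phantom generation is deterministic and errors on oversized lesions", {
  a <- small_phantom(); b <- small_phantom()
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_error(
    phantom_params(grid_shape = c(16, 16, 64), lesion_radius_mm = c(20, 5, 5)),
    "axis x")
})

test_that("voxelized ellipsoid volume is close to the analytic volume", {
  p <- phantom_params(grid_shape = c(32, 32, 32), spacing = c(1, 1, 1),
                      lesion_radius_mm = c(10, 10, 10), noise_sd = 0)
  ph <- generate_phantom(p, 1)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(mask_volume_mm3(ph$mask) - analytic) / analytic, 0.05)
})

test_that("zero perturbation reproduces the true mask exactly", {
  ph <- small_phantom()
  prof <- observer_profile("MR", 0, 0)
  out <- simulate_delineation(ph$mask, profile = prof, observer = 1,
                              session = 1, seed = 3)
  expect_identical(out$data, ph$mask$data)
})

test_that("nonzero perturbation changes the mask but stays reproducible", {
  ph <- small_phantom()
  prof <- observer_profile("CECT", 1, 2)
  d1 <- simulate_delineation(ph$mask, profile = prof, observer = 1,
                             session = 1, seed = 5)
  d2 <- simulate_delineation(ph$mask, profile = prof, observer = 1,
                             session = 2, seed = 5)
  d1b <- simulate_delineation(ph$mask, profile = prof, observer = 1,
                              session = 1, seed = 5)
  expect_identical(d1$data, d1b$data)
  expect_lt(dice_coefficient(ph$mask, d1), 1)
  expect_lt(dice_coefficient(ph$mask, d2), 1)
  expect_false(identical(d1$data, d2$data))
  # same observer two sessions overlap more than two different observers
  d3 <- simulate_delineation(ph$mask, profile = prof, observer = 2,
                             session = 1, seed = 5)
  expect_gt(dice_coefficient(d1, d2), dice_coefficient(d1, d3))
})

test_that("lower-sigma profiles give higher mean Dice with the truth", {
  ph <- small_phantom()
  profs <- default_observer_profiles()
  mean_dice <- function(prof, seeds) {
    mean(vapply(seeds, function(s)
      dice_coefficient(ph$mask, simulate_delineation(
        ph$mask, profile = prof, observer = 1, session = 1, seed = s)),
      numeric(1)))
  }
  seeds <- 1:50
  d_mr <- mean_dice(profs$MR, seeds)
  d_cect <- mean_dice(profs$CECT, seeds)
  d_mip <- mean_dice(profs$MIP, seeds)
  expect_gt(d_mr, d_cect)
  expect_gt(d_cect, d_mip)
})

test_that("mean Dice decreases monotonically with sigma", {
  ph <- small_phantom()
  dice_at <- function(sig) {
    prof <- observer_profile("X", sig, sig)
    mean(vapply(1:20, function(s) {
      d <- dice_coefficient(ph$mask, simulate_delineation(
        ph$mask, profile = prof, observer = 1, session = 1, seed = s))
      expect_gt(d, 0); expect_lte(d, 1)
      d
    }, numeric(1)))
  }
  dd <- vapply(c(0.5, 1.5, 3), dice_at, numeric(1))
  expect_true(all(diff(dd) < 0))
})

test_that("cohort record count equals the design product for random designs", {
  set.seed(99)
  ph_small <- phantom_params(grid_shape = c(24, 24, 16),
                             lesion_radius_mm = c(6, 6, 6))
  for (rep in 1:5) {
    des <- study_design(
      n_subjects = sample(1:3, 1),
      modalities = sample(c("CECT", "MIP", "MR"), sample(1:3, 1)),
      observers = sample(1:2, 1), sessions = sample(1:2, 1),
      tissues = if (runif(1) < 0.5) "tumor" else c("tumor", "peritumor"),
      master_seed = sample(1e6, 1))
    b <- generate_cohort(des, phantom = ph_small)
    expect_equal(nrow(b$records), design_record_count(des))
  }
})

test_that("minimal 1x1x1x1 design with both tissues yields 2 records", {
  des <- study_design(n_subjects = 1, modalities = "MR", observers = 1,
                      sessions = 1, master_seed = 5)
  b <- generate_cohort(des, phantom = phantom_params(
    grid_shape = c(24, 24, 16), lesion_radius_mm = c(6, 6, 6)))
  expect_equal(nrow(b$records), 2L)
  expect_setequal(b$records$tissue, c("tumor", "peritumor"))
})

test_that("cohort regeneration from the master seed is bit-identical", {
  des <- study_design(n_subjects = 2, master_seed = 31)
  ph <- phantom_params(grid_shape = c(24, 24, 16),
                       lesion_radius_mm = c(6, 6, 6))
  b1 <- generate_cohort(des, phantom = ph)
  b2 <- generate_cohort(des, phantom = ph)
  expect_identical(b1$records, b2$records)
  expect_identical(lapply(b1$masks, `[[`, "idx"),
                   lapply(b2$masks, `[[`, "idx"))
  expect_identical(b1$images[[1]]$data, b2$images[[1]]$data)
  # arm labelling convention: index 1,2 = observer 1, 3,4 = observer 2
  r <- b1$records
  expect_true(all(r$arm_label[r$observer == 1 & r$session == 2] %in%
                    paste0(c("CECT", "MIP", "MR"), 2)))
  expect_true(all(r$arm_label[r$observer == 2 & r$session == 1] %in%
                    paste0(c("CECT", "MIP", "MR"), 3)))
})
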