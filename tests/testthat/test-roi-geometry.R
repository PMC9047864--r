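# Mask containers, alignment checks, volume, and peritumoral ring geometry.

test_that("mask construction validates values and geometry", {
  expect_error(roi_mask(array(c(0, 2), c(2, 1, 1))), "0 or 1")
  expect_error(image_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  m <- roi_mask(array(c(TRUE, FALSE), c(2, 1, 1)))
  expect_identical(as.vector(m$data), c(1L, 0L))
})

test_that("mask volume is voxel count times voxel volume", {
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  expect_equal(mask_volume_mm3(roi_mask(m, spacing = c(0.97, 0.97, 3.0))),
               0.97 * 0.97 * 3.0)
  expect_equal(mask_volume_mm3(roi_mask(array(0L, c(2, 2, 2)))), 0)
  cube <- roi_mask(array(1L, c(10, 10, 10)))
  expect_equal(mask_volume_mm3(cube), 1000)
})

test_that("alignment report lists mismatches and respects tolerance", {
  img <- image_volume(array(0, c(4, 4, 4)))
  expect_length(validate_alignment(img, roi_mask(array(0L, c(4, 4, 4)))), 0)
  rep1 <- validate_alignment(img, roi_mask(array(0L, c(4, 4, 5))))
  expect_length(rep1, 1)
  expect_match(rep1, "axis z")
  # spacing within 1e-4 mm tolerance is accepted
  near <- roi_mask(array(0L, c(4, 4, 4)), spacing = c(1, 1, 1 + 1e-6))
  expect_length(validate_alignment(img, near), 0)
})

test_that("unit-spacing ring of radius 1 around a voxel is its 6 face neighbours", {
  m <- array(0L, c(7, 7, 7)); m[4, 4, 4] <- 1L
  ring <- peritumoral_ring(roi_mask(m), radius_mm = 1)
  expect_equal(sum(ring$data), 6)
  co <- arrayInd(which(ring$data == 1L), dim(ring$data))
  expect_true(all(rowSums(abs(co - 4)) == 1))
})

test_that("anisotropic ring respects physical distances per axis", {
  # spacing 0.97 x 0.97 x 3.0, radius 2.9 mm: nothing along z (3.0 > 2.9),
  # up to 2 in-plane steps (1.94 mm)
  m <- array(0L, c(9, 9, 9)); m[5, 5, 5] <- 1L
  ring <- peritumoral_ring(roi_mask(m, spacing = c(0.97, 0.97, 3.0)),
                           radius_mm = 2.9)
  co <- arrayInd(which(ring$data == 1L), dim(ring$data))
  expect_true(all(co[, 3] == 5))
  expect_equal(max(abs(co[, 1:2] - 5)), 2)
  d <- sqrt(((co[, 1] - 5) * 0.97)^2 + ((co[, 2] - 5) * 0.97)^2)
  expect_true(all(d <= 2.9 & d > 0))
})

test_that("ring is disjoint from the GTV and clipped at the boundary", {
  m <- array(0L, c(8, 8, 8)); m[1:3, 1:3, 1:2] <- 1L  # touches the boundary
  ring <- peritumoral_ring(roi_mask(m), radius_mm = 5)
  expect_equal(sum(ring$data & m), 0)
  expect_identical(dim(ring$data), dim(m))
  expect_error(peritumoral_ring(roi_mask(array(0L, c(4, 4, 4)))), "empty")
})

test_that("ring voxel count is non-decreasing in radius", {
  set.seed(42)
  m <- array(0L, c(16, 16, 8))
  m[6:10, 6:11, 3:5] <- 1L
  msk <- roi_mask(m, spacing = c(0.97, 0.97, 3.0))
  counts <- vapply(1:10, function(r)
    sum(peritumoral_ring(msk, radius_mm = r)$data), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ring union GTV equals brute-force distance-transform dilation", {
  set.seed(7)
  for (rep in 1:3) {
    d <- c(12L, 10L, 8L)
    sp <- c(1.1, 0.9, 2.0)
    m <- array(0L, d)
    seedvox <- cbind(sample(4:9, 3), sample(3:8, 3), sample(3:6, 3))
    m[seedvox] <- 1L
    gtv <- roi_mask(m, spacing = sp)
    radius <- sample(c(2, 3.5, 5), 1)
    ring <- peritumoral_ring(gtv, radius_mm = radius)
    # oracle: per-voxel minimum spacing-weighted distance to any GTV voxel
    all_co <- arrayInd(seq_len(prod(d)), d)
    gtv_co <- arrayInd(which(m == 1L), d)
    mind <- apply(all_co, 1, function(v) {
      dd <- sweep(gtv_co, 2, v, `-`)
      sqrt(min(colSums((t(dd) * sp)^2)))
    })
    expected_union <- as.integer(mind <= radius)
    got_union <- as.integer((ring$data | m))
    expect_identical(got_union, as.vector(expected_union))
  }
})
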