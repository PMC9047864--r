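# Hand-enumerable texture-matrix cases and structural invariants.

const_roi <- function(dims, value = 50) {
  tiny_roi(rep(value, prod(dims)), dims = dims)
}

test_that("GLCM of a constant 2x2x1 ROI concentrates at (1,1)", {
  tr <- const_roi(c(2, 2, 1))
  # single gray level: the degenerate-correlation warning is expected
  g <- suppressWarnings(glcm_features(tr$disc))
  expect_length(g, 24)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["MaximumProbability"]), 1)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEnergy"]), 1)
})

test_that("single-voxel ROI yields the zero-matrix convention", {
  tr <- const_roi(c(1, 1, 1))
  expect_warning(g <- glcm_features(tr$disc), "degenerate")
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_true(all(g == 0))
})

test_that("GLRLM counts one run of length 4 along the row direction", {
  tr <- tiny_roi(rep(10, 4), dims = c(4, 1, 1))
  P <- radrepro:::build_glrlm_one(
    radrepro:::crop_discretized(tr$disc)$levels, c(1L, 0L, 0L), 1L, 4L)
  expect_equal(sum(P), 1)
  expect_equal(P[1, 4], 1)
  f <- radrepro:::glrlm_features_one(P, 4)
  expect_equal(unname(f["ShortRunEmphasis"]), 1 / 16)
})

test_that("constant ROI has normalized gray-level non-uniformity 1 (GLRLM)", {
  tr <- const_roi(c(3, 3, 2))
  f <- glrlm_features(tr$disc)
  expect_length(f, 16)
  expect_equal(unname(f["GrayLevelNonUniformityNormalized"]), 1)
})

test_that("GLSZM sees a constant 3x3x1 ROI as one zone of size 9", {
  tr <- const_roi(c(3, 3, 1))
  f <- glszm_features(tr$disc)
  expect_length(f, 16)
  expect_equal(unname(f["ZonePercentage"]), 1 / 9)
  expect_equal(unname(f["LargeAreaEmphasis"]), 81)
  expect_equal(unname(f["SmallAreaEmphasis"]), 1 / 81)
})

test_that("alternating 1xN row gives N single-voxel zones", {
  vals <- rep(c(0, 50), 4)  # levels alternate 1,3,1,3 -> 8 zones of size 1
  tr <- tiny_roi(vals, dims = c(8, 1, 1))
  f <- glszm_features(tr$disc)
  expect_equal(unname(f["ZonePercentage"]), 1)
  expect_equal(unname(f["SmallAreaEmphasis"]), 1)
})

test_that("GLDM dependence histogram of a constant 3x3x1 ROI is as enumerated", {
  # centre voxel has 8 equal neighbours (dependence 9), edges 5 (dep 6),
  # corners 3 (dep 4): histogram {4 x dep4, 4 x dep6, 1 x dep9}
  tr <- const_roi(c(3, 3, 1))
  f <- gldm_features(tr$disc)
  expect_length(f, 14)
  p <- c(4, 4, 1) / 9
  expect_equal(unname(f["DependenceEntropy"]), -sum(p * log2(p)))
  expect_equal(unname(f["LargeDependenceEmphasis"]),
               (4 * 16 + 4 * 36 + 81) / 9)
})

test_that("single voxel has dependence 1 and zero dependence entropy", {
  tr <- const_roi(c(1, 1, 1))
  f <- gldm_features(tr$disc)
  expect_equal(unname(f["DependenceEntropy"]), 0)
  expect_equal(unname(f["LargeDependenceEmphasis"]), 1)
})

test_that("NGTDM contrast matches the hand-computed two-level strip", {
  # levels 1,1,2 in a row: s_1 = 0 + 0.5, s_2 = 1, p = (2/3, 1/3)
  tr <- tiny_roi(c(0, 0, 25), dims = c(3, 1, 1))
  f <- ngtdm_features(tr$disc)
  expect_length(f, 5)
  expect_equal(unname(f["Contrast"]), 1 / 9)
  expect_equal(unname(f["Coarseness"]),
               1 / ((2 / 3) * 0.5 + (1 / 3) * 1))
})

test_that("constant ROI has zero NGTDM contrast and capped coarseness", {
  tr <- const_roi(c(3, 3, 2))
  f <- ngtdm_features(tr$disc)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Coarseness"]), 1e6)
})

test_that("normalized texture matrices sum to 1 on random phantoms", {
  set.seed(11)
  for (rep in 1:20) {
    dims <- c(sample(4:8, 1), sample(4:8, 1), sample(3:6, 1))
    vals <- rnorm(prod(dims), 100, 40)
    tr <- tiny_roi(vals, dims = dims)
    ctx <- radrepro:::texture_context(tr$disc)
    for (m in radrepro:::build_glcm(ctx$lev, ctx$n_levels, ctx$pairs)) {
      if (sum(m) > 0) expect_equal(sum(m / sum(m)), 1)
    }
    P <- radrepro:::build_glrlm_one(ctx$lev, c(1L, 1L, 0L), ctx$n_levels,
                                    max(dims))
    expect_equal(sum(P / sum(P)), 1)
  }
})

test_that("texture features are invariant to whole-voxel translation", {
  cs <- oracle_phantom_case(1)
  fv <- extract_all_features(cs$image, cs$mask)
  d <- dim(cs$image$data)
  big_img <- array(0, d + c(4, 3, 2))
  big_msk <- array(0L, d + c(4, 3, 2))
  big_img[3:(d[1] + 2), 2:(d[2] + 1), 3:(d[3] + 2)] <- cs$image$data
  big_msk[3:(d[1] + 2), 2:(d[2] + 1), 3:(d[3] + 2)] <- cs$mask$data
  fv2 <- extract_all_features(image_volume(big_img, cs$image$spacing),
                              roi_mask(big_msk, cs$mask$spacing))
  expect_equal(fv, fv2, tolerance = 1e-12)
})

test_that("adding a bin-width multiple leaves all texture features unchanged", {
  cs <- oracle_phantom_case(2)
  fv <- extract_all_features(cs$image, cs$mask)
  shifted <- image_volume(cs$image$data + 3 * 25, cs$image$spacing)
  fv2 <- extract_all_features(shifted, cs$mask)
  texture <- grep("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(fv), value = TRUE)
  expect_equal(fv[texture], fv2[texture], tolerance = 1e-12)
  expect_equal(unname(fv2["firstorder_Mean"] - fv["firstorder_Mean"]), 75)
})
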