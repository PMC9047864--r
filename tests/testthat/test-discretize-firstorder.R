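# Fixed-bin-width discretization and first-order features.

test_that("discretization follows the min-anchored floor rule", {
  tr <- tiny_roi(c(0, 10, 30, 60), dims = c(4, 1, 1))
  expect_setequal(tr$disc$levels[!is.na(tr$disc$levels)], c(1L, 1L, 2L, 3L))
  expect_equal(tr$disc$n_levels, 3L)
})

test_that("discretization handles negative intensities", {
  tr <- tiny_roi(c(-30, -10), dims = c(2, 1, 1))
  expect_identical(sort(tr$disc$levels[!is.na(tr$disc$levels)]), c(1L, 2L))
})

test_that("constant ROI discretizes to a single level", {
  tr <- tiny_roi(rep(42, 8), dims = c(2, 2, 2))
  expect_true(all(tr$disc$levels == 1L))
  expect_equal(tr$disc$n_levels, 1L)
})

test_that("first-order features match hand arithmetic on {1,2,3,4}", {
  tr <- tiny_roi(1:4, dims = c(4, 1, 1))
  fo <- first_order_features(tr$image, tr$mask, tr$disc)
  expect_equal(unname(fo["Mean"]), 2.5)
  expect_equal(unname(fo["Range"]), 3)
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(7.5))
  expect_equal(unname(fo["Energy"]), 30)
  expect_equal(unname(fo["Variance"]), 1.25)   # population moment
  expect_equal(unname(fo["Minimum"]), 1)
  expect_equal(unname(fo["Maximum"]), 4)
})

test_that("degenerate constant ROI uses the documented conventions", {
  tr <- tiny_roi(rep(7, 10), dims = c(10, 1, 1))
  fo <- first_order_features(tr$image, tr$mask, tr$disc)
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Entropy"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["Skewness"]), 0)
  expect_equal(unname(fo["Kurtosis"]), 0)
})

test_that("first-order emits exactly the 18 reference features", {
  tr <- tiny_roi(c(3, 1, 4, 1, 5, 9, 2, 6), dims = c(2, 2, 2))
  fo <- first_order_features(tr$image, tr$mask, tr$disc)
  expect_length(fo, 18)
  expect_true(all(is.finite(fo)))
})
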