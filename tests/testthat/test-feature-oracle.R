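# Cross-implementation check: the full 107-feature vector against frozen
# values from an independently coded Python oracle (numpy/scipy texture
# matrices, scikit-image marching cubes + trimesh mesh geometry), regenerated
# with tools/oracle/freeze_oracle.R.

test_that("extract_all_features emits 107 features with the documented classes", {
  cs <- oracle_phantom_case(1)
  fv <- extract_all_features(cs$image, cs$mask)
  expect_length(fv, 107)
  counts <- table(sub("_.*$", "", names(fv)))
  expect_equal(as.vector(counts[c("firstorder", "glcm", "gldm", "glrlm",
                                  "glszm", "ngtdm", "shape")]),
               c(18L, 24L, 14L, 16L, 16L, 5L, 14L))
  expect_identical(names(fv), feature_name_table()$name)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all_features(cs$image, cs$mask))
})

test_that("all 107 features agree with the independent oracle on 5 phantoms", {
  orc <- read.csv(test_path("oracle-feature-values.csv"),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(orc), 5 * 107)
  for (i in 1:5) {
    cs <- oracle_phantom_case(i)
    fv <- extract_all_features(cs$image, cs$mask)
    o <- orc[orc$case == i, ]
    mine <- fv[o$name]
    is_shape <- grepl("^shape_", o$name)
    rel <- abs(mine - o$value) / pmax(abs(o$value), 1e-12)
    expect_lt(max(rel[!is_shape]), 1e-5)
    expect_lt(max(rel[is_shape]), 1e-2)
  }
})
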