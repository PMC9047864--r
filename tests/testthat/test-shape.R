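# Mesh-based shape features.

test_that("unit cube voxel has unit voxel volume and a closed unit surface", {
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  expect_warning(sf <- shape_features(roi_mask(m)), "single-voxel")
  expect_equal(unname(sf["VoxelVolume"]), 1)
  # marching cubes at level 0.5 shrinks a lone voxel to an octahedron of
  # half-diagonal 0.5: volume 1/6, area sqrt(3)/2 * ... checked numerically
  expect_gt(unname(sf["MeshVolume"]), 0)
  expect_equal(unname(sf["MajorAxisLength"]), 0)
  expect_length(sf, 14)
})

test_that("voxelized ball shape summaries match analytic references", {
  d <- 27L; ctr <- 14
  g <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  m <- array(as.integer((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 121),
             c(d, d, d))
  sf <- shape_features(roi_mask(m))
  vol <- 4 / 3 * pi * 11^3
  expect_lt(abs(sf["MeshVolume"] - vol) / vol, 0.05)
  expect_equal(unname(sf["Maximum3DDiameter"]), 23)   # 22 voxel steps + caps
  # binary marching cubes keeps a staircase residual: the sphericity of a
  # voxelized ball plateaus near 0.91 rather than reaching 1
  expect_gt(unname(sf["Sphericity"]), 0.85)
  expect_lte(unname(sf["Sphericity"]), 1)
  expect_equal(unname(sf["Elongation"]), 1, tolerance = 0.02)
  expect_equal(unname(sf["Flatness"]), 1, tolerance = 0.02)
})

test_that("anisotropic spacing scales the physical axes", {
  m <- array(0L, c(12, 12, 12)); m[4:9, 4:9, 4:9] <- 1L
  iso <- shape_features(roi_mask(m))
  aniso <- shape_features(roi_mask(m, spacing = c(1, 1, 3)))
  expect_equal(unname(aniso["VoxelVolume"]), 3 * unname(iso["VoxelVolume"]))
  expect_equal(unname(aniso["Maximum2DDiameterSlice"]),
               unname(iso["Maximum2DDiameterSlice"]))
  expect_gt(unname(aniso["Maximum2DDiameterColumn"]),
            unname(iso["Maximum2DDiameterColumn"]))
})

test_that("pruned diameter search equals the exhaustive scan", {
  set.seed(5)
  for (rep in 1:5) {
    m <- array(0L, c(10, 9, 8))
    n <- sample(20:60, 1)
    m[cbind(sample(2:9, n, TRUE), sample(2:8, n, TRUE),
            sample(2:7, n, TRUE))] <- 1L
    m <- radrepro:::largest_component(m)
    sp <- c(1.1, 0.9, 2.3)
    mesh <- radrepro:::build_mask_mesh(as.integer(m), dim(m), sp)
    ms <- radrepro:::mesh_summaries(mesh$vertices, mesh$faces)
    V <- mesh$vertices
    dm <- as.matrix(dist(V))
    expect_equal(ms$max_diameter_3d, max(dm), tolerance = 1e-12)
    dxy <- as.matrix(dist(V[, 1:2]))
    expect_equal(ms$max_diameter_xy, max(dxy), tolerance = 1e-12)
    dyz <- as.matrix(dist(V[, 2:3]))
    expect_equal(ms$max_diameter_yz, max(dyz), tolerance = 1e-12)
  }
})
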