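# 3D shape features (14) from the triangulated mask surface (marching cubes
# at the 0.5 level, vertices in physical mm) and from the PCA of foreground
# voxel-center coordinates. Axis lengths are 4*sqrt(eigenvalue) of the
# (sample) covariance of physical coordinates; degenerate masks (single
# voxel / coplanar) report 0 for the affected lengths with a warning.

shape_feature_names <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")

#' Shape features of a binary mask (14)
#'
#' Surface area, mesh volume and maximum diameters come from the marching
#' cubes surface of the mask; the three 2D diameters are the largest
#' pairwise vertex distances after projection onto the axial (`Slice`, x-y),
#' coronal (`Column`, y-z) and sagittal (`Row`, x-z) planes. Axis lengths
#' come from the principal axes of the voxel-center point cloud.
#'
#' @param mask A non-empty [roi_mask()].
#' @param spacing Optional spacing override (mm).
#' @return Named numeric vector of 14 features (lengths in mm, areas in mm^2,
#'   volumes in mm^3).
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  if (sum(mask$data) == 0L) stop("mask is empty")
  bb <- mask_bbox(mask$data)
  sub <- crop_to_bbox(mask$data, bb)
  mesh <- build_mask_mesh(as.integer(sub), dim(sub), as.numeric(spacing))
  ms <- mesh_summaries(mesh$vertices, mesh$faces)
  n <- sum(sub)
  co <- sweep(arrayInd(which(sub != 0L), dim(sub)) - 1, 2, spacing, `*`)
  if (n > 1) {
    ev <- sort(eigen(stats::cov(co), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    warning("single-voxel mask: axis lengths degenerate, reported as 0")
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  vol <- ms$volume
  out <- c(
    MeshVolume = vol,
    VoxelVolume = n * prod(spacing),
    SurfaceArea = ms$surface_area,
    SurfaceVolumeRatio = ms$surface_area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / ms$surface_area,
    Maximum3DDiameter = ms$max_diameter_3d,
    Maximum2DDiameterSlice = ms$max_diameter_xy,
    Maximum2DDiameterColumn = ms$max_diameter_yz,
    Maximum2DDiameterRow = ms$max_diameter_xz,
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = elong,
    Flatness = flat)
  out[shape_feature_names]
}
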