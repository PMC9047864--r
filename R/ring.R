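# Peritumoral ring construction on anisotropic grids.
#
# Distances are spacing-weighted Euclidean distances between voxel centers, so
# "radius in mm" keeps its meaning when in-plane and through-plane spacings
# differ (e.g. 0.97 x 0.97 x 3.0 mm CT grids).

# Integer voxel offsets whose physical length is <= radius_mm (excluding the
# zero offset). Each row is (dx, dy, dz).
ball_offsets <- function(spacing, radius_mm) {
  m <- floor(radius_mm / spacing)
  g <- expand.grid(dx = -m[1]:m[1], dy = -m[2]:m[2], dz = -m[3]:m[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  keep <- d2 <= radius_mm^2 & d2 > 0
  as.matrix(g[keep, , drop = FALSE])
}

# Binary dilation of `arr` by the set of voxel offsets within radius_mm,
# i.e. the set of voxels whose center lies within radius_mm of some
# foreground voxel center. Exact for the voxel-center distance definition.
dilate_ball <- function(arr, spacing, radius_mm) {
  d <- dim(arr)
  off <- ball_offsets(spacing, radius_mm)
  out <- arr != 0L
  src <- arr != 0L
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    xs <- max(1L, 1L + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1L, 1L + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1L, 1L + o[3]):min(d[3], d[3] + o[3])
    out[xs, ys, zs] <- out[xs, ys, zs] | src[xs - o[1], ys - o[2], zs - o[3]]
  }
  out
}

#' Peritumoral ring around a GTV mask
#'
#' Voxels whose spacing-weighted Euclidean distance (mm, between voxel
#' centers) to the nearest GTV voxel is greater than 0 and at most
#' `radius_mm`. The ring is disjoint from the GTV by construction and is
#' clipped at the grid boundary.
#'
#' @param gtv Non-empty [roi_mask()].
#' @param spacing Optional spacing override (mm); defaults to the mask's own.
#' @param radius_mm Ring outer radius in mm (default 5, the 0-5 mm shell).
#' @return An [roi_mask()] on the same grid. May be empty (with a warning)
#'   when `radius_mm` is below the smallest voxel step on every axis.
#' @export
peritumoral_ring <- function(gtv, spacing = NULL, radius_mm = 5) {
  stopifnot(inherits(gtv, "roi_mask"))
  if (is.null(spacing)) spacing <- gtv$spacing
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    stop("`radius_mm` must be a single positive number")
  if (sum(gtv$data) == 0L) stop("GTV mask is empty; cannot build a ring")
  d <- dim(gtv$data)
  pad <- pmin(floor(radius_mm / spacing), d)  # margin needed around the GTV
  bb <- mask_bbox(gtv$data, pad = as.integer(pad))
  sub <- crop_to_bbox(gtv$data, bb)
  dil <- dilate_ball(sub, spacing, radius_mm)
  ring_sub <- dil & !(sub != 0L)
  ring <- array(0L, dim = d)
  ring[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <-
    as.integer(ring_sub)
  if (!any(ring != 0L))
    warning("peritumoral ring is empty: radius_mm = ", radius_mm,
            " is below the voxel step on every axis")
  roi_mask(ring, gtv$spacing, gtv$origin)
}
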