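# 26-connected component labelling (compiled flood fill) used by zone
# matrices and by the delineation simulator's largest-component cleanup.

# The 13 unique positive 3D neighbour offsets (half of the 26-neighbourhood).
OFFSETS13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, , drop = FALSE])
})

# For one offset, linear indices (i1, i2) of all in-grid voxel pairs.
offset_pairs <- function(d, o) {
  lo <- pmax(1L, 1L - o); hi <- pmin(d, d - o)
  if (any(hi < lo)) return(NULL)   # offset exceeds the grid on some axis
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  i1 <- as.vector(outer(outer(xs, (ys - 1L) * d[1], `+`),
                        (zs - 1L) * d[1] * d[2], `+`))
  i2 <- as.vector(outer(outer(xs + o[1], (ys + o[2] - 1L) * d[1], `+`),
                        (zs + o[3] - 1L) * d[1] * d[2], `+`))
  cbind(i1, i2)
}

# Label 26-connected zones of equal value in `lev` (NA = background).
# Returns an integer array of zone labels (NA outside), labels 1..n_zones.
label_zones <- function(lev) {
  lv <- lev
  lv[is.na(lv)] <- 0L
  storage.mode(lv) <- "integer"
  lab <- label_zones_cpp(as.vector(lv), dim(lev))
  lab[lab == 0L] <- NA_integer_
  array(lab, dim = dim(lev))
}

# Keep only the largest 26-connected foreground component of a binary array.
largest_component <- function(arr) {
  lab <- label_zones_cpp(as.integer(arr != 0L), dim(arr))
  if (!any(lab != 0L)) return(array(0L, dim = dim(arr)))
  tab <- tabulate(lab[lab != 0L])
  array(as.integer(lab == which.max(tab)), dim = dim(arr))
}
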