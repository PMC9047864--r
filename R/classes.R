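#' 3D image volume with physical geometry
#'
#' Container for a 3D scalar voxel grid together with its physical geometry.
#' Voxel indices are 1-based in R; the physical position of voxel
#' `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing` (millimetres).
#'
#' @param data Numeric 3D array of voxel intensities.
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin Numeric length-3, physical position of the first voxel (mm).
#' @return An object of class `image_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (length(data) == 0L) stop("`data` must be non-empty")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary region-of-interest mask
#'
#' A binary voxel mask on the same grid as its companion [image_volume()].
#' Values must be 0/1 (logical input is coerced).
#'
#' @param data 3D array with values in \{0, 1\} (or logical).
#' @param spacing,origin Grid geometry, as for [image_volume()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    bad <- data[!(data %in% c(0, 1))]
    if (length(bad))
      stop("mask values must be 0 or 1; found value ", format(bad[[1]]))
    storage.mode(data) <- "integer"
  }
  vol <- image_volume(data, spacing, origin)
  structure(list(data = vol$data, spacing = vol$spacing, origin = vol$origin),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(format(x$spacing), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = "x"),
      " voxels, ", sum(x$data), " foreground, spacing ",
      paste(format(x$spacing), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Number of foreground voxels
#' @param mask An [roi_mask()].
#' @return Integer count.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$data)
}

#' Physical mask volume in cubic millimetres
#'
#' Foreground voxel count times the voxel volume. An empty mask has volume 0.
#'
#' @param mask An [roi_mask()].
#' @param spacing Optional spacing override (mm); defaults to the mask's own.
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  sum(mask$data) * prod(spacing)
}

#' Check that an image and a mask share one grid
#'
#' Compares array shape, spacing (tolerance 1e-4 mm) and origin
#' (tolerance 1e-4 mm). Returns a report rather than erroring so callers can
#' decide how strict to be.
#'
#' @param image An [image_volume()].
#' @param mask An [roi_mask()] (or second image).
#' @param tol Geometric tolerance in mm.
#' @return Character vector of mismatch descriptions; empty when aligned.
#' @export
validate_alignment <- function(image, mask, tol = 1e-4) {
  report <- character(0)
  di <- dim(image$data); dm <- dim(mask$data)
  ax <- c("x", "y", "z")
  for (a in 1:3) {
    if (di[a] != dm[a])
      report <- c(report, sprintf(
        "shape mismatch on axis %s: image %d vs mask %d", ax[a], di[a], dm[a]))
    if (abs(image$spacing[a] - mask$spacing[a]) > tol)
      report <- c(report, sprintf(
        "spacing mismatch on axis %s: %g vs %g mm",
        ax[a], image$spacing[a], mask$spacing[a]))
    if (abs(image$origin[a] - mask$origin[a]) > tol)
      report <- c(report, sprintf(
        "origin mismatch on axis %s: %g vs %g mm",
        ax[a], image$origin[a], mask$origin[a]))
  }
  report
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return `2|A n B| / (|A| + |B|)`; `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"),
            identical(dim(a$data), dim(b$data)))
  denom <- sum(a$data) + sum(b$data)
  if (denom == 0) return(NaN)
  2 * sum(a$data & b$data) / denom
}

# Bounding box of the foreground, optionally padded (clipped to the grid).
# Returns list(lo, hi) of 1-based index triples, or NULL for an empty mask.
mask_bbox <- function(arr, pad = c(0L, 0L, 0L)) {
  idx <- which(arr != 0)
  if (!length(idx)) return(NULL)
  d <- dim(arr)
  co <- arrayInd(idx, d)
  lo <- pmax(apply(co, 2, min) - pad, 1L)
  hi <- pmin(apply(co, 2, max) + pad, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_to_bbox <- function(arr, bb) {
  arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

# Compact storage for one delineation inside a cohort bundle: foreground
# linear indices plus grid geometry (a full 64^3 array per record would be
# wasteful at 456 records).
pack_mask <- function(mask) {
  structure(list(dim = dim(mask$data), idx = which(mask$data != 0L),
                 spacing = mask$spacing, origin = mask$origin),
            class = "packed_mask")
}

#' Materialize a packed cohort mask as an [roi_mask()]
#' @param pm A `packed_mask` as stored in a cohort bundle record.
#' @return An [roi_mask()].
#' @export
unpack_mask <- function(pm) {
  stopifnot(inherits(pm, "packed_mask"))
  arr <- array(0L, dim = pm$dim)
  arr[pm$idx] <- 1L
  roi_mask(arr, pm$spacing, pm$origin)
}
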