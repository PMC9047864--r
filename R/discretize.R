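#' Fixed-bin-width gray-level discretization of an ROI
#'
#' Maps ROI intensities to integer gray levels with bins of constant width,
#' anchored so the minimum ROI intensity falls in level 1:
#' `level(x) = floor(x / bin_width) - floor(min / bin_width) + 1`.
#' Because the anchor is `floor(min / bin_width)` (not `min` itself), adding
#' any whole multiple of `bin_width` to the image leaves all levels, and
#' hence all texture features, unchanged.
#'
#' @param image An [image_volume()].
#' @param mask A non-empty [roi_mask()] on the same grid.
#' @param bin_width Bin width in intensity units (default 25).
#' @return A `discretized_roi`: `levels` (3D integer array, `NA` outside the
#'   ROI), `n_levels`, `bin_width`, `values` (original ROI intensities),
#'   `spacing`.
#' @export
discretize_fixed_bin_width <- function(image, mask, bin_width = 25) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  mis <- validate_alignment(image, mask)
  if (length(mis)) stop("image/mask not aligned: ", paste(mis, collapse = "; "))
  fg <- mask$data != 0L
  if (!any(fg)) stop("mask is empty")
  vals <- image$data[fg]
  lev_fg <- as.integer(floor(vals / bin_width) -
                         floor(min(vals) / bin_width) + 1)
  levels <- array(NA_integer_, dim = dim(image$data))
  levels[fg] <- lev_fg
  structure(list(levels = levels, n_levels = max(lev_fg),
                 bin_width = bin_width, values = vals,
                 spacing = image$spacing),
            class = "discretized_roi")
}

# Crop a discretized ROI to the foreground bounding box (texture matrices
# only need the ROI neighbourhood; full-grid arrays waste time).
crop_discretized <- function(disc) {
  bb <- mask_bbox(!is.na(disc$levels) + 0L)
  disc$levels <- crop_to_bbox(disc$levels, bb)
  disc
}
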