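#' Extract the full 107-feature radiomic vector
#'
#' Concatenates the seven feature classes in a fixed, documented order:
#' first-order (18), shape (14), GLCM (24), GLRLM (16), GLSZM (16),
#' GLDM (14), NGTDM (5). Names are `class_FeatureName` (e.g.
#' `glcm_JointEntropy`). Intensities are discretized once with a fixed bin
#' width (default 25) and shared by all texture classes; no resampling or
#' image filtering is applied.
#'
#' @param image An [image_volume()].
#' @param mask A non-empty [roi_mask()] aligned with `image`.
#' @param bin_width Fixed bin width for gray-level discretization.
#' @return Named numeric vector with exactly 107 entries.
#' @export
extract_all_features <- function(image, mask, bin_width = 25) {
  mis <- validate_alignment(image, mask)
  if (length(mis)) stop("image/mask not aligned: ", paste(mis, collapse = "; "))
  if (sum(mask$data) == 0L) stop("mask is empty")
  disc <- discretize_fixed_bin_width(image, mask, bin_width)
  ctx <- texture_context(disc)
  wrap <- function(class_label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s features failed: %s", class_label,
                   conditionMessage(e)), call. = FALSE))
  }
  fo <- wrap("first-order", first_order_features(image, mask, disc))
  sh <- wrap("shape", shape_features(mask))
  gl <- wrap("GLCM", glcm_features(disc, ctx))
  rl <- wrap("GLRLM", glrlm_features(disc, ctx))
  sz <- wrap("GLSZM", glszm_features(disc, ctx))
  dm <- wrap("GLDM", gldm_features(disc, ctx))
  nt <- wrap("NGTDM", ngtdm_features(disc, ctx))
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(sh, paste0("shape_", names(sh))),
           stats::setNames(gl, paste0("glcm_", names(gl))),
           stats::setNames(rl, paste0("glrlm_", names(rl))),
           stats::setNames(sz, paste0("glszm_", names(sz))),
           stats::setNames(dm, paste0("gldm_", names(dm))),
           stats::setNames(nt, paste0("ngtdm_", names(nt))))
  stopifnot(length(out) == 107L)
  out
}

#' Canonical 107 feature names with class tags
#'
#' @return Data frame with columns `name` (prefixed feature name) and
#'   `class`.
#' @export
feature_name_table <- function() {
  data.frame(
    name = c(paste0("firstorder_", first_order_feature_names),
             paste0("shape_", shape_feature_names),
             paste0("glcm_", glcm_feature_names),
             paste0("glrlm_", glrlm_feature_names),
             paste0("glszm_", glszm_feature_names),
             paste0("gldm_", gldm_feature_names),
             paste0("ngtdm_", ngtdm_feature_names)),
    class = rep(c("firstorder", "shape", "glcm", "glrlm", "glszm", "gldm",
                  "ngtdm"),
                times = c(18, 14, 24, 16, 16, 14, 5)),
    stringsAsFactors = FALSE)
}

#' Feature table for every delineation record of a cohort
#'
#' Runs [extract_all_features()] for each record of a [generate_cohort()]
#' bundle against its subject's phantom image.
#'
#' @param bundle A `cohort_bundle`.
#' @param bin_width Fixed bin width for discretization.
#' @param verbose Print progress every 50 records.
#' @return Data frame: record metadata columns followed by 107 feature
#'   columns.
#' @export
cohort_feature_table <- function(bundle, bin_width = 25, verbose = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  recs <- bundle$records
  feats <- matrix(NA_real_, nrow(recs), 107,
                  dimnames = list(NULL, feature_name_table()$name))
  for (i in seq_len(nrow(recs))) {
    img <- bundle$images[[recs$subject[i]]]
    msk <- unpack_mask(bundle$masks[[i]])
    feats[i, ] <- extract_all_features(img, msk, bin_width)
    if (verbose && i %% 50L == 0L)
      message("extracted ", i, "/", nrow(recs), " records")
  }
  cbind(recs, as.data.frame(feats))
}
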