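# First-order intensity statistics (18 features). Percentiles use linear
# interpolation between order statistics (R quantile type 7); entropy and
# uniformity are computed on the fixed-bin-width discretized levels (log2);
# moments are population moments (divide by N). Degenerate (constant) ROIs
# report skewness and kurtosis as 0 by convention.

first_order_feature_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

#' First-order features of an ROI
#'
#' @param image An [image_volume()].
#' @param mask A non-empty [roi_mask()].
#' @param disc Optional precomputed [discretize_fixed_bin_width()] result;
#'   computed with the default bin width when missing.
#' @param bin_width Bin width used when `disc` is missing.
#' @return Named numeric vector of the 18 first-order features.
#' @export
first_order_features <- function(image, mask, disc = NULL, bin_width = 25) {
  if (is.null(disc)) disc <- discretize_fixed_bin_width(image, mask, bin_width)
  x <- disc$values
  n <- length(x)
  vv <- prod(disc$spacing)
  p <- tabulate(disc$levels[!is.na(disc$levels)], nbins = disc$n_levels) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  out[first_order_feature_names]
}
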