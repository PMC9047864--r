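# Human-readable summaries of the screening results, in the "77/107 (72.0%)"
# style; underlying CSVs keep full precision.

#' Render a count out of a total as "n/total (pct%)"
#'
#' @param n Count(s).
#' @param total Denominator (default 107 features).
#' @param digits Decimal places for the percentage (default 1).
#' @return Character vector like `"77/107 (72.0%)"`.
#' @export
format_fraction <- function(n, total = 107, digits = 1) {
  sprintf(paste0("%d/%d (%.", digits, "f%%)"), n, total,
          100 * n / total)
}

#' Summary tables of a reliability screening
#'
#' @param counts Output of [count_meeting()].
#' @param robust Character vector of robust features (optional).
#' @param total Number of features screened.
#' @return List of data frames: `icc_by_pair` (count and rendered fraction
#'   per tissue x comparison), `icc_group_means` (mean count per tissue x
#'   modality x intra/inter group), `qcd_by_arm`, and `robust`.
#' @export
report_counts <- function(counts, robust = NULL, total = 107) {
  icc <- counts$icc_counts
  icc_by_pair <- NULL
  icc_group_means <- NULL
  if (!is.null(icc)) {
    icc_by_pair <- icc
    icc_by_pair$rendered <- format_fraction(icc$n_meeting, total)
    icc$modality <- sub("[0-9]+/.*$", "", icc$comparison)
    icc_group_means <- stats::aggregate(
      list(mean_count = icc$n_meeting),
      by = list(tissue = icc$tissue, modality = icc$modality,
                pair_type = icc$pair_type),
      FUN = mean)
    icc_group_means$rendered <- format_fraction(
      round(icc_group_means$mean_count), total)
  }
  qcd_by_arm <- NULL
  if (!is.null(counts$qcd_counts)) {
    qcd_by_arm <- counts$qcd_counts
    qcd_by_arm$rendered <- format_fraction(qcd_by_arm$n_meeting, total)
  }
  list(icc_by_pair = icc_by_pair, icc_group_means = icc_group_means,
       qcd_by_arm = qcd_by_arm,
       robust = if (is.null(robust)) NULL else data.frame(feature = robust))
}
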