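# Reliability screening of radiomic features: quartile coefficient of
# dispersion (QCD) per arm, two-way random-effects single-measure
# absolute-agreement ICC per arm pair, the published threshold taxonomies,
# and robust-feature selection.

#' Quartile coefficient of dispersion
#'
#' `QCD = (Q3 - Q1) / (Q3 + Q1) * 100`, with quartiles by linear
#' interpolation between order statistics (R quantile type 7). For data where
#' `Q3 + Q1 <= 0` (possible for signed features such as skewness) the QCD is
#' undefined and `NA` is returned; undefined QCD never counts as a small
#' variation downstream.
#'
#' @param values Numeric vector, length >= 2.
#' @param quantile_type Quantile algorithm (see [stats::quantile()]).
#' @return QCD in percent, or `NA_real_` when undefined.
#' @export
qcd <- function(values, quantile_type = 7) {
  if (length(values) < 2L) stop("QCD needs at least 2 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE,
                       type = quantile_type)
  if ((q[2] + q[1]) <= 0) return(NA_real_)
  (q[2] - q[1]) / (q[2] + q[1]) * 100
}

#' Two-way random-effects, single-measure, absolute-agreement ICC
#'
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`, with
#' mean squares from the standard two-way ANOVA decomposition of a complete
#' subjects x raters matrix (`MS_R` rows/subjects, `MS_C` columns/raters,
#' `MS_E` residual). Equals ICC(2,1) / ICC(A,1). A constant matrix has no
#' subject variance to apportion and returns `NA` with an explanation
#' attribute.
#'
#' @param ratings Numeric matrix, subjects in rows (n >= 2), raters in
#'   columns (k >= 2), no missing cells.
#' @return List with `icc` and `anova` (list: `ms_rows`, `ms_cols`,
#'   `ms_error`, `n`, `k`).
#' @export
icc_two_way <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("ICC needs >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stop("ICC requires a complete ratings matrix")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm - grand)^2)
  resid <- ratings - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand
  ss_err <- sum(resid^2)
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  anova <- list(ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
                n = n, k = k)
  denom <- ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err)
  if (denom <= 0) {
    icc <- NA_real_
    attr(icc, "reason") <- "constant ratings: no variance to apportion"
  } else {
    icc <- (ms_rows - ms_err) / denom
  }
  list(icc = icc, anova = anova)
}

#' Classify an ICC value by the reliability taxonomy
#'
#' `< 0.4` poor, `0.4-0.59` fair, `0.6-0.74` good, `>= 0.75` excellent.
#'
#' @param icc ICC value(s); `NA` maps to `"undefined"`.
#' @return Character vector of classes.
#' @export
classify_icc <- function(icc) {
  out <- ifelse(is.na(icc), "undefined",
         ifelse(icc < 0.4, "poor",
         ifelse(icc < 0.6, "fair",
         ifelse(icc < 0.75, "good", "excellent"))))
  unname(out)
}

#' Classify a QCD value by the variation taxonomy
#'
#' `< 10` small, `10-20` intermediate, `>= 20` large (percent); `NA` maps to
#' `"undefined"`.
#'
#' @param q QCD value(s) in percent.
#' @return Character vector of classes.
#' @export
classify_qcd <- function(q) {
  out <- ifelse(is.na(q), "undefined",
         ifelse(q < 10, "small",
         ifelse(q < 20, "intermediate", "large")))
  unname(out)
}

# Arm pairs for a 4-arm modality: (1,2) and (3,4) are the two intra-observer
# pairs (same observer, repeat sessions); the other four are inter-observer.
arm_pairs_4 <- function() {
  data.frame(a = c(1L, 3L, 1L, 1L, 2L, 2L), b = c(2L, 4L, 3L, 4L, 3L, 4L),
             type = c("intra", "intra", rep("inter", 4)),
             stringsAsFactors = FALSE)
}

#' Pairwise ICC screening across the four arms of one modality
#'
#' Computes, per feature, the two-way random-effects absolute-agreement ICC
#' for each of the six unordered arm pairs; pairs (1,2) and (3,4) are
#' intra-observer, the remaining four inter-observer.
#'
#' @param tables Named list of 4 per-arm feature matrices/data frames
#'   (subjects x features) with identical subject sets (row order) and
#'   identical feature columns; names are the arm labels.
#' @param tissue Tissue label carried through to the output.
#' @return Data frame: `feature`, `comparison` (e.g. `"MR1/MR2"`), `tissue`,
#'   `pair_type` (`intra`/`inter`), `icc`, `icc_class`.
#' @export
pairwise_icc <- function(tables, tissue = NA_character_) {
  if (length(tables) != 4L) stop("pairwise ICC expects exactly 4 arms")
  labs <- names(tables)
  tabs <- lapply(tables, function(tb) as.matrix(as.data.frame(tb)))
  ns <- vapply(tabs, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("arms have different subject counts: ", paste(ns, collapse = ", "))
  feats <- colnames(tabs[[1]])
  for (tb in tabs) if (!identical(colnames(tb), feats))
    stop("arms have different feature columns")
  pairs <- arm_pairs_4()
  out <- vector("list", nrow(pairs) * length(feats))
  idx <- 0L
  for (pi in seq_len(nrow(pairs))) {
    a <- pairs$a[pi]; b <- pairs$b[pi]
    for (f in feats) {
      icc <- icc_two_way(cbind(tabs[[a]][, f], tabs[[b]][, f]))$icc
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        feature = f, comparison = paste0(labs[a], "/", labs[b]),
        tissue = tissue, pair_type = pairs$type[pi],
        icc = as.numeric(icc), icc_class = classify_icc(icc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-arm QCD of every feature
#'
#' @param tables Named list of per-arm feature matrices (subjects x
#'   features).
#' @param tissue Tissue label carried through.
#' @return Data frame: `feature`, `arm`, `tissue`, `qcd`, `qcd_class`.
#' @export
arm_qcd <- function(tables, tissue = NA_character_) {
  out <- list()
  for (arm in names(tables)) {
    tb <- as.matrix(as.data.frame(tables[[arm]]))
    q <- apply(tb, 2, qcd)
    out[[arm]] <- data.frame(feature = colnames(tb), arm = arm,
                             tissue = tissue, qcd = as.numeric(q),
                             qcd_class = classify_qcd(q),
                             stringsAsFactors = FALSE)
  }
  rn <- do.call(rbind, out)
  rownames(rn) <- NULL
  rn
}

#' Count features meeting the reliability / variation thresholds
#'
#' @param icc_records Output of [pairwise_icc()] (possibly row-bound over
#'   modalities/tissues).
#' @param qcd_records Output of [arm_qcd()] (same).
#' @param icc_threshold ICC threshold, met when `icc >= icc_threshold`.
#' @param qcd_threshold QCD threshold in percent, met when
#'   `qcd < qcd_threshold` (undefined QCD never counts).
#' @return List of two data frames: `icc_counts` (per tissue x comparison)
#'   and `qcd_counts` (per tissue x arm).
#' @export
count_meeting <- function(icc_records, qcd_records = NULL,
                          icc_threshold = 0.75, qcd_threshold = 10) {
  icc_counts <- NULL
  if (!is.null(icc_records)) {
    ok <- !is.na(icc_records$icc) & icc_records$icc >= icc_threshold
    icc_counts <- stats::aggregate(
      list(n_meeting = ok),
      by = list(tissue = icc_records$tissue,
                comparison = icc_records$comparison,
                pair_type = icc_records$pair_type),
      FUN = sum)
  }
  qcd_counts <- NULL
  if (!is.null(qcd_records)) {
    okq <- !is.na(qcd_records$qcd) & qcd_records$qcd < qcd_threshold
    qcd_counts <- stats::aggregate(
      list(n_meeting = okq),
      by = list(tissue = qcd_records$tissue, arm = qcd_records$arm),
      FUN = sum)
  }
  list(icc_counts = icc_counts, qcd_counts = qcd_counts)
}

#' Select robust features from tumor and peritumor screening records
#'
#' A feature is robust when it shows excellent reliability
#' (`icc >= icc_threshold`) in every listed comparison and small variation
#' (`qcd < qcd_threshold`, defined) in every listed arm, in both tissues.
#' With `semantics = "any"` one passing comparison/arm per tissue suffices.
#'
#' @param icc_records Row-bound [pairwise_icc()] records for both tissues
#'   (typically the MR-guided modality only).
#' @param qcd_records Row-bound [arm_qcd()] records for both tissues.
#' @param icc_threshold,qcd_threshold Selection thresholds.
#' @param semantics `"all"` (default) or `"any"` over comparisons/arms.
#' @return Character vector of robust feature names (possibly empty).
#' @export
select_robust <- function(icc_records, qcd_records,
                          icc_threshold = 0.75, qcd_threshold = 10,
                          semantics = c("all", "any")) {
  semantics <- match.arg(semantics)
  agg <- if (semantics == "all") all else any
  tissues <- unique(icc_records$tissue)
  feats <- unique(icc_records$feature)
  keep <- vapply(feats, function(f) {
    for (tis in tissues) {
      ic <- icc_records$icc[icc_records$feature == f &
                              icc_records$tissue == tis]
      qc <- qcd_records$qcd[qcd_records$feature == f &
                              qcd_records$tissue == tis]
      if (!length(ic) || !length(qc)) return(FALSE)
      icc_ok <- agg(!is.na(ic) & ic >= icc_threshold)
      qcd_ok <- agg(!is.na(qc) & qc < qcd_threshold)
      if (!(icc_ok && qcd_ok)) return(FALSE)
    }
    TRUE
  }, logical(1))
  feats[keep]
}

#' Arrange a cohort feature table into per-arm matrices
#'
#' @param feature_table Output of [cohort_feature_table()].
#' @param modality Modality to extract.
#' @param tissue Tissue to extract.
#' @return Named list of subjects x features matrices, one per arm label,
#'   rows ordered by subject.
#' @export
arm_feature_tables <- function(feature_table, modality, tissue) {
  sel <- feature_table$modality == modality & feature_table$tissue == tissue
  ft <- feature_table[sel, , drop = FALSE]
  meta <- c("record", "subject", "tissue", "modality", "observer", "session",
            "arm_label")
  arms <- sort(unique(ft$arm_label))
  out <- lapply(arms, function(a) {
    sub <- ft[ft$arm_label == a, , drop = FALSE]
    sub <- sub[order(sub$subject), , drop = FALSE]
    m <- as.matrix(sub[, setdiff(colnames(ft), meta), drop = FALSE])
    rownames(m) <- sub$subject
    m
  })
  names(out) <- arms
  subj <- lapply(out, rownames)
  if (length(unique(vapply(subj, paste, "", collapse = ","))) != 1L) {
    all_s <- sort(unique(unlist(subj)))
    missing <- lapply(subj, function(s) setdiff(all_s, s))
    stop("arms cover different subjects: ",
         paste(vapply(seq_along(missing), function(i)
           if (length(missing[[i]])) paste0(names(out)[i], " lacks ",
                paste(missing[[i]], collapse = ",")) else "",
           ""), collapse = " "))
  }
  out
}
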