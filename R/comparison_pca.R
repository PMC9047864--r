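# Tumor vs peritumor discrimination of robust features and PCA
# dimensionality reduction with a variance-retention criterion.

#' Compare a feature between tumor and peritumor tissue
#'
#' If both groups pass Shapiro-Wilk normality at `alpha`, a one-way ANOVA
#' (equal-variance F test) is used; otherwise Kruskal-Wallis. Two identical
#' constant groups are degenerate: p is reported as 1 with `degenerate =
#' TRUE`.
#'
#' @param tumor,peritumor Numeric vectors, >= 3 observations each.
#' @param alpha Significance level for both the normality routing and the
#'   significance flag.
#' @return List: `feature` test `statistic`, `p_value`, `test`
#'   (`"anova"`/`"kruskal"`), `significant`, `degenerate`, `group_means`.
#' @export
compare_tissues <- function(tumor, peritumor, alpha = 0.05) {
  if (length(tumor) < 3L || length(peritumor) < 3L)
    stop("need at least 3 observations per group")
  gm <- c(tumor = mean(tumor), peritumor = mean(peritumor))
  if (stats::var(tumor) == 0 && stats::var(peritumor) == 0 &&
      tumor[1] == peritumor[1]) {
    return(list(statistic = NA_real_, p_value = 1, test = "degenerate",
                significant = FALSE, degenerate = TRUE, group_means = gm))
  }
  normal <- function(x) {
    if (stats::var(x) == 0) return(FALSE)  # Shapiro undefined for constants
    stats::shapiro.test(x)$p.value >= alpha
  }
  x <- c(tumor, peritumor)
  g <- factor(rep(c("tumor", "peritumor"), c(length(tumor),
                                             length(peritumor))))
  if (normal(tumor) && normal(peritumor)) {
    ht <- stats::oneway.test(x ~ g, var.equal = TRUE)
    test <- "anova"
  } else {
    ht <- stats::kruskal.test(x ~ g)
    test <- "kruskal"
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test,
       significant = ht$p.value < alpha, degenerate = FALSE,
       group_means = gm)
}

#' Correlation-matrix PCA of a subjects x features matrix
#'
#' Columns are z-scored before the eigendecomposition (feature scales differ
#' by orders of magnitude); zero-variance columns are dropped with a
#' warning.
#'
#' @param features Numeric matrix or data frame, subjects in rows.
#' @return List: `eigenvalues` (descending), `proportion`, `cumulative`,
#'   `n90` (smallest component count retaining >= 90% of variance),
#'   `scores`, `dropped` (names of zero-variance columns).
#' @export
pca_reduce <- function(features) {
  X <- as.matrix(as.data.frame(features))
  if (nrow(X) < 2L) stop("PCA needs at least 2 subjects")
  v <- apply(X, 2, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 1L) stop("no non-constant features left for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  cum <- cumsum(prop)
  list(eigenvalues = ev, proportion = prop, cumulative = cum,
       n90 = n_components_for(list(cumulative = cum), 0.90),
       scores = pc$x, dropped = dropped)
}

#' Number of components retaining a variance fraction
#'
#' @param pca A [pca_reduce()] result (or any list with `cumulative`).
#' @param fraction Target fraction in (0, 1].
#' @return Smallest integer m with cumulative proportion >= `fraction`.
#' @export
n_components_for <- function(pca, fraction = 0.90) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1)
    stop("`fraction` must be in (0, 1]")
  cum <- pca$cumulative
  m <- which(cum >= fraction - 1e-12)
  if (!length(m)) length(cum) else min(m)
}
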