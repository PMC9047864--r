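# Gray-level texture matrices and their features. All matrices are built on
# the fixed-bin-width discretized ROI at Chebyshev distance 1 over the 13
# unique 3D directions (their 26 signed counterparts for neighbourhood-based
# matrices); per-direction features are averaged with equal weight. Log terms
# use base 2 and skip zero cells. Degenerate denominators follow a
# return-0-with-warning convention (NGTDM coarseness is capped at 1e6).

glcm_feature_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "MCC", "SumAverage", "SumEntropy", "SumSquares")

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

gldm_feature_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

ngtdm_feature_names <- c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

# Shared per-ROI context so the texture classes do not rebuild the cropped
# level array, neighbour-pair index tables and neighbour statistics five
# times per extraction.
texture_context <- function(disc) {
  lev <- crop_discretized(disc)$levels
  d <- dim(lev)
  pairs <- lapply(seq_len(nrow(OFFSETS13)),
                  function(r) offset_pairs(d, OFFSETS13[r, ]))
  list(lev = lev, n_levels = disc$n_levels, pairs = pairs,
       nstats = neighbour_stats(lev, pairs))
}

zero_features <- function(names, class_label) {
  warning("degenerate ROI (no neighbour structure): ", class_label,
          " features set to 0", call. = FALSE)
  stats::setNames(rep(0, length(names)), names)
}

xlog2x <- function(p) {
  p <- p[p > 0]
  sum(p * log2(p))
}

# ---------------------------------------------------------------- GLCM ----

# Symmetric co-occurrence count matrices at distance 1, one per direction.
build_glcm <- function(lev, n_levels, pairs) {
  out <- vector("list", nrow(OFFSETS13))
  for (r in seq_len(nrow(OFFSETS13))) {
    pr <- pairs[[r]]
    m <- matrix(0, n_levels, n_levels)
    if (!is.null(pr)) {
      a <- lev[pr[, 1]]; b <- lev[pr[, 2]]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        tb <- tabulate((a[ok] - 1L) * n_levels + b[ok],
                       nbins = n_levels * n_levels)
        m <- matrix(tb, n_levels, n_levels, byrow = TRUE)
        m <- m + t(m)  # symmetrize: count each pair in both orders
      }
    }
    out[[r]] <- m
  }
  out
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal-sum and anti-diagonal distributions
  kdiff <- 0:(ng - 1)
  pxmy <- vapply(kdiff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  pxpy <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))
  hx <- -xlog2x(px); hy <- -xlog2x(py)
  hxy <- -xlog2x(P)
  pp <- outer(px, py)
  hxy1 <- -sum(P[pp > 0] * log2(pp[pp > 0]))
  hxy2 <- -xlog2x(pp)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * P) - mux * muy) / (sigx * sigy) else {
      warning("flat GLCM: correlation set to 0", call. = FALSE); 0
    }
  mcc <- if (ng == 1) 1 else {
    safe_px <- ifelse(px > 0, px, 1)
    safe_py <- ifelse(py > 0, py, 1)
    # Q(a, b) = sum_k p(a, k) p(b, k) / (px(a) py(k))
    Q <- (P / safe_px) %*% t(sweep(P, 2, safe_py, `/`))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  da <- sum(kdiff * pxmy)
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -xlog2x(pxmy),
    DifferenceVariance = sum((kdiff - da)^2 * pxmy),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(pxmy[-1] / kdiff[-1]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(ksum * pxpy),
    SumEntropy = -xlog2x(pxpy),
    SumSquares = sum((i - mux)^2 * P))
}

#' Gray-level co-occurrence matrix features (24)
#'
#' Symmetric GLCMs at distance 1 for the 13 unique 3D directions; each is
#' normalized and the 24 features are averaged over directions with equal
#' weight. Directions without any voxel pair are skipped.
#'
#' @param disc A [discretize_fixed_bin_width()] result.
#' @param ctx Optional precomputed texture context (internal use).
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(disc, ctx = NULL) {
  if (is.null(ctx)) ctx <- texture_context(disc)
  mats <- build_glcm(ctx$lev, ctx$n_levels, ctx$pairs)
  mats <- Filter(function(m) sum(m) > 0, mats)
  if (!length(mats)) return(zero_features(glcm_feature_names, "GLCM"))
  per <- vapply(mats, function(m) glcm_features_one(m / sum(m)),
                numeric(length(glcm_feature_names)))
  rowMeans(per)[glcm_feature_names]
}

# --------------------------------------------------------------- GLRLM ----

# Run-length count matrix (levels x run length) for one direction.
build_glrlm_one <- function(lev, o, n_levels, max_len) {
  d <- dim(lev)
  idx <- arrayInd(seq_along(lev), d)
  t_axis <- if (o[3] != 0) 3L else if (o[2] != 0) 2L else 1L
  tt <- idx[, t_axis]           # increments by +1 along the direction
  lid <- idx - tt %*% t(o)      # constant along each line
  M <- max(d) * 3               # lid components lie within (-M, 2M)
  key <- (lid[, 1] + M) + (lid[, 2] + M) * (4 * M) +
    (lid[, 3] + M) * (16 * M^2)
  ord <- order(key, tt)
  lv <- lev[ord]; ky <- key[ord]
  brk <- c(TRUE, diff(ky) != 0)
  same <- c(FALSE, lv[-1] == lv[-length(lv)])
  same[is.na(same)] <- FALSE    # NA (outside ROI) always breaks a run
  run_id <- cumsum(brk | !same)
  keep <- !is.na(lv)
  if (!any(keep)) return(matrix(0, n_levels, max_len))
  r <- run_id[keep]             # sorted by construction
  starts <- which(c(TRUE, diff(r) != 0))
  runs <- diff(c(starts, length(r) + 1L))
  run_lev <- lv[keep][starts]
  tb <- tabulate((run_lev - 1L) * max_len + pmin(runs, max_len),
                 nbins = n_levels * max_len)
  matrix(tb, n_levels, max_len, byrow = TRUE)
}

glrlm_features_one <- function(P, n_voxels) {
  nr <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nr
  pg <- rowSums(P); pr <- colSums(P)
  mug <- sum(row(p) * p); mur <- sum(col(p) * p)
  c(ShortRunEmphasis = sum(P / j^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum((i - mug)^2 * p),
    RunVariance = sum((j - mur)^2 * p),
    RunEntropy = -xlog2x(p),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

#' Gray-level run-length matrix features (16)
#'
#' Run-length matrices along the 13 unique 3D directions (voxels outside the
#' ROI break runs); 16 features averaged over directions.
#'
#' @param disc A [discretize_fixed_bin_width()] result.
#' @param ctx Optional precomputed texture context (internal use).
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc, ctx = NULL) {
  if (is.null(ctx)) ctx <- texture_context(disc)
  lev <- ctx$lev
  n_vox <- sum(!is.na(lev))
  max_len <- max(dim(lev))
  per <- apply(OFFSETS13, 1, function(o) {
    P <- build_glrlm_one(lev, as.integer(o), ctx$n_levels, max_len)
    if (sum(P) == 0) return(rep(NA_real_, length(glrlm_feature_names)))
    glrlm_features_one(P, n_vox)
  })
  if (all(is.na(per[1, ])))
    return(zero_features(glrlm_feature_names, "GLRLM"))
  stats::setNames(rowMeans(per, na.rm = TRUE), glrlm_feature_names)
}

# --------------------------------------------------------------- GLSZM ----

#' Gray-level size-zone matrix features (16)
#'
#' Zones are 26-connected components of equal gray level; a single matrix
#' (levels x zone size) summarizes the whole ROI.
#'
#' @param disc A [discretize_fixed_bin_width()] result.
#' @param ctx Optional precomputed texture context (internal use).
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(disc, ctx = NULL) {
  if (is.null(ctx)) ctx <- texture_context(disc)
  lev <- ctx$lev
  lab <- label_zones(lev)
  keep <- !is.na(lab)
  sizes <- tabulate(lab[keep])
  zl <- lev[keep][!duplicated(lab[keep])]
  zone_lab <- lab[keep][!duplicated(lab[keep])]
  zlev <- zl[order(zone_lab)]
  n_vox <- sum(keep)
  nz <- length(sizes)
  smax <- max(sizes)
  P <- matrix(tabulate((zlev - 1L) * smax + sizes,
                       nbins = ctx$n_levels * smax),
              ctx$n_levels, smax, byrow = TRUE)
  i <- row(P); j <- col(P)
  p <- P / nz
  pg <- rowSums(P); ps <- colSums(P)
  mug <- sum(i * p); mus <- sum(j * p)
  out <- c(SmallAreaEmphasis = sum(P / j^2) / nz,
           LargeAreaEmphasis = sum(P * j^2) / nz,
           GrayLevelNonUniformity = sum(pg^2) / nz,
           GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
           SizeZoneNonUniformity = sum(ps^2) / nz,
           SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
           ZonePercentage = nz / n_vox,
           GrayLevelVariance = sum((i - mug)^2 * p),
           ZoneVariance = sum((j - mus)^2 * p),
           ZoneEntropy = -xlog2x(p),
           LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
           HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
           SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
           SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
           LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
           LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
  out[glszm_feature_names]
}

# ---------------------------------------------------------------- GLDM ----

# For each ROI voxel: number of 26-neighbours inside the ROI with equal
# level (dependence threshold alpha = 0), and the sum/count of neighbour
# levels (shared with NGTDM).
neighbour_stats <- function(lev, pairs) {
  d <- dim(lev)
  eq <- array(0L, dim = d)
  nsum <- array(0, dim = d)
  ncount <- array(0L, dim = d)
  for (r in seq_len(nrow(OFFSETS13))) {
    pr <- pairs[[r]]
    if (is.null(pr)) next
    a <- pr[, 1]; b <- pr[, 2]
    ok <- !is.na(lev[a]) & !is.na(lev[b])
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    same <- as.integer(lev[a] == lev[b])
    # for a fixed offset each voxel occurs at most once in `a` and once in
    # `b`, so plain indexed addition is safe
    eq[a] <- eq[a] + same;          eq[b] <- eq[b] + same
    nsum[a] <- nsum[a] + lev[b];    nsum[b] <- nsum[b] + lev[a]
    ncount[a] <- ncount[a] + 1L;    ncount[b] <- ncount[b] + 1L
  }
  list(eq = eq, nsum = nsum, ncount = ncount)
}

#' Gray-level dependence matrix features (14)
#'
#' Dependence of a voxel = 1 + number of 26-neighbours inside the ROI with
#' the same gray level (threshold alpha = 0).
#'
#' @param disc A [discretize_fixed_bin_width()] result.
#' @param ctx Optional precomputed texture context (internal use).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(disc, ctx = NULL) {
  if (is.null(ctx)) ctx <- texture_context(disc)
  lev <- ctx$lev
  ns <- ctx$nstats
  fg <- !is.na(lev)
  dep <- ns$eq[fg] + 1L
  lv <- lev[fg]
  dmax <- max(dep)
  P <- matrix(tabulate((lv - 1L) * dmax + dep, nbins = ctx$n_levels * dmax),
              ctx$n_levels, dmax, byrow = TRUE)
  nz <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nz
  pg <- rowSums(P); pd <- colSums(P)
  mug <- sum(i * p); mud <- sum(j * p)
  out <- c(SmallDependenceEmphasis = sum(P / j^2) / nz,
           LargeDependenceEmphasis = sum(P * j^2) / nz,
           GrayLevelNonUniformity = sum(pg^2) / nz,
           DependenceNonUniformity = sum(pd^2) / nz,
           DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
           GrayLevelVariance = sum((i - mug)^2 * p),
           DependenceVariance = sum((j - mud)^2 * p),
           DependenceEntropy = -xlog2x(p),
           LowGrayLevelEmphasis = sum(P / i^2) / nz,
           HighGrayLevelEmphasis = sum(P * i^2) / nz,
           SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
           SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
           LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
           LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
  out[gldm_feature_names]
}

# --------------------------------------------------------------- NGTDM ----

#' Neighbourhood gray-tone difference matrix features (5)
#'
#' For each ROI voxel with at least one ROI 26-neighbour, the absolute
#' difference between its level and the mean level of those neighbours is
#' accumulated per gray level; coarseness, contrast, busyness, complexity
#' and strength follow. Coarseness is capped at 1e6 when its denominator
#' is 0.
#'
#' @param disc A [discretize_fixed_bin_width()] result.
#' @param ctx Optional precomputed texture context (internal use).
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc, ctx = NULL) {
  if (is.null(ctx)) ctx <- texture_context(disc)
  lev <- ctx$lev
  ns <- ctx$nstats
  fg <- !is.na(lev) & ns$ncount > 0L
  if (!any(fg)) return(zero_features(ngtdm_feature_names, "NGTDM"))
  lv <- lev[fg]
  abar <- ns$nsum[fg] / ns$ncount[fg]
  ng <- ctx$n_levels
  n_i <- tabulate(lv, nbins = ng)
  s_i <- numeric(ng)
  agg <- rowsum(abs(lv - abar), lv)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  lvls <- seq_len(ng)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    pij <- outer(p_i[present], p_i[present])
    dij <- outer(lvls[present], lvls[present], `-`)
    contrast <- (sum(pij * dij^2) / (ngp * (ngp - 1))) * (sum(s_i) / nvp)
    ipi <- lvls[present] * p_i[present]
    busy_den <- sum(abs(outer(ipi, ipi, `-`)))
    busyness <- if (busy_den > 0) coarse_den / busy_den else 0
    psum <- outer(p_i[present], p_i[present], `+`)
    snum <- outer(p_i[present] * s_i[present], p_i[present] * s_i[present], `+`)
    complexity <- sum(abs(dij) * snum / psum) / nvp
    strength_num <- sum(psum * dij^2)
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength),
                  ngtdm_feature_names)
}
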