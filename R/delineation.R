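# Simulated manual delineation: the true lesion surface is displaced along
# the radial direction by a smooth band-limited random field on the sphere
# (real spherical harmonics up to degree 2), split into an observer-level
# component shared across that observer's sessions and an independent
# session-level component. This emulates correlated contour deviation —
# observers disagree smoothly over whole surface patches, not voxel by voxel.

#' Observer delineation-variability profile
#'
#' @param modality One of `"CECT"`, `"MIP"`, `"MR"` (label only).
#' @param sigma_intra_mm SD (mm) of the session-level radial perturbation —
#'   repeat delineation by the same observer.
#' @param sigma_inter_mm SD (mm) of the observer-level radial perturbation —
#'   systematic differences between observers. Must be >= `sigma_intra_mm`.
#' @param bias_mm Systematic over- (positive) or under-segmentation (mm).
#' @return An `observer_profile` list.
#' @export
observer_profile <- function(modality, sigma_intra_mm, sigma_inter_mm,
                             bias_mm = 0) {
  if (sigma_intra_mm < 0 || sigma_inter_mm < 0)
    stop("perturbation SDs must be >= 0")
  if (sigma_intra_mm > sigma_inter_mm)
    stop("sigma_intra_mm must not exceed sigma_inter_mm")
  structure(list(modality = modality, sigma_intra_mm = sigma_intra_mm,
                 sigma_inter_mm = sigma_inter_mm, bias_mm = bias_mm),
            class = "observer_profile")
}

#' Default per-modality delineation profiles
#'
#' Encodes the qualitative ordering of boundary conspicuity: lesions are
#' easiest to contour consistently on multi-parameter MR, harder on CECT and
#' hardest on MIP, so sigma(MR) < sigma(CECT) < sigma(MIP).
#'
#' @return Named list of [observer_profile()] objects (CECT, MIP, MR).
#' @export
default_observer_profiles <- function() {
  list(CECT = observer_profile("CECT", 1.0, 2.0),
       MIP  = observer_profile("MIP",  1.5, 3.0),
       MR   = observer_profile("MR",   0.5, 1.0))
}

# Real orthonormal spherical harmonics, degrees 0..2, at unit vectors (rows
# of u). Returns an n x 9 matrix; sum over the 9 columns of Y^2 is 9/(4*pi)
# for every direction, so i.i.d. N(0, sigma^2 * 4*pi/9) coefficients give a
# field with pointwise SD exactly sigma.
sh_basis_l2 <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(
    0.28209479177387814,
    0.4886025119029199 * y,
    0.4886025119029199 * z,
    0.4886025119029199 * x,
    1.0925484305920792 * x * y,
    1.0925484305920792 * y * z,
    0.31539156525252005 * (3 * z^2 - 1),
    1.0925484305920792 * x * z,
    0.5462742152960396 * (x^2 - y^2)
  )
}

sh_coefficients <- function(sigma_mm, seed) {
  if (sigma_mm == 0) return(rep(0, 9))
  with_seed(seed, stats::rnorm(9, sd = sigma_mm * sqrt(4 * pi / 9)))
}

#' Simulate one manual delineation of a true mask
#'
#' Displaces the true surface radially (about the mask centroid) by
#' `bias_mm` plus a smooth observer-level random field (SD
#' `sigma_inter_mm`, shared by the same observer across sessions) plus a
#' smooth session-level field (SD `sigma_intra_mm`). With all three zero the
#' output equals the input exactly. The result is reduced to its largest
#' 26-connected component.
#'
#' @param true_mask Non-empty ground-truth [roi_mask()].
#' @param spacing Optional spacing override (mm).
#' @param profile An [observer_profile()].
#' @param observer,session Integer identifiers; the observer id selects the
#'   shared observer-level field, the session id the session-level field.
#' @param seed Integer seed for this subject x modality stream; child seeds
#'   are derived per observer and session.
#' @return A perturbed [roi_mask()] on the same grid.
#' @export
simulate_delineation <- function(true_mask, spacing = NULL, profile,
                                 observer = 1L, session = 1L, seed = 1L) {
  stopifnot(inherits(true_mask, "roi_mask"), inherits(profile, "observer_profile"))
  if (is.null(spacing)) spacing <- true_mask$spacing
  arr <- true_mask$data
  if (sum(arr) == 0L) stop("true_mask is empty")
  co_obs <- sh_coefficients(profile$sigma_inter_mm,
                            child_seed(seed, "observer", observer))
  co_ses <- sh_coefficients(profile$sigma_intra_mm,
                            child_seed(seed, "observer", observer,
                                       "session", session))
  if (all(co_obs == 0) && all(co_ses == 0) && profile$bias_mm == 0)
    return(true_mask)

  d <- dim(arr)
  fg <- which(arr != 0L)
  co <- arrayInd(fg, d)
  centroid <- colMeans(sweep(co - 1, 2, spacing, `*`))
  # evaluation region: true bounding box padded by the plausible outward growth
  grow_mm <- abs(profile$bias_mm) +
    3.5 * (profile$sigma_inter_mm + profile$sigma_intra_mm)
  pad <- as.integer(ceiling(grow_mm / spacing) + 1L)
  bb <- mask_bbox(arr, pad = pad)
  xs <- bb$lo[1]:bb$hi[1]; ys <- bb$lo[2]:bb$hi[2]; zs <- bb$lo[3]:bb$hi[3]
  gi <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  p <- sweep(gi - 1, 2, spacing, `*`)
  p <- sweep(p, 2, centroid, `-`)
  r <- sqrt(rowSums(p^2))
  u <- p / pmax(r, 1e-12)
  f <- profile$bias_mm + as.vector(sh_basis_l2(u) %*% (co_obs + co_ses))
  # a voxel at radius r lies inside the displaced mask iff the point at
  # radius r - f along the same direction lies inside the true mask
  ratio <- pmax(r - f, 0) / pmax(r, 1e-12)
  ratio[r == 0] <- 0
  q <- sweep(p * ratio, 2, centroid, `+`)
  qi <- round(sweep(q, 2, spacing, `/`)) + 1
  inside <- qi[, 1] >= 1 & qi[, 1] <= d[1] &
    qi[, 2] >= 1 & qi[, 2] <= d[2] &
    qi[, 3] >= 1 & qi[, 3] <= d[3]
  val <- rep(0L, nrow(qi))
  if (any(inside)) {
    lin <- (qi[inside, 3] - 1) * d[1] * d[2] + (qi[inside, 2] - 1) * d[1] +
      qi[inside, 1]
    val[inside] <- arr[lin]
  }
  out <- array(0L, dim = d)
  out[cbind(gi[, 1], gi[, 2], gi[, 3])] <- val
  if (!any(out != 0L))
    stop("perturbation annihilated the mask; use a smaller sigma or bias")
  out <- largest_component(out)
  roi_mask(out, true_mask$spacing, true_mask$origin)
}
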