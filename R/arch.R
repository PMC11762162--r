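#' Dental arch curve
#'
#' An ordered polyline `r(c) = (x(c), y(c))`, `c = 0..Nc-1`, in voxel
#' coordinates of the axial plane, with unit normals `n(c)` perpendicular to
#' the local tangent and oriented buccally (away from the curve centroid),
#' resampled at equal arc length.
#'
#' @param points Nc x 2 matrix of (x, y) voxel coordinates.
#' @param normals Nc x 2 matrix of unit normals.
#' @return object of class `arch_curve`.
#' @export
arch_curve <- function(points, normals) {
  points <- as.matrix(points); normals <- as.matrix(normals)
  stopifnot(nrow(points) == nrow(normals), ncol(points) == 2)
  seglen <- sqrt(rowSums(diff(points)^2))
  if (any(seglen == 0)) stop("consecutive curve points must be distinct")
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) stop("normals must have unit length")
  tg <- diff(points)
  tg <- rbind(tg, tg[nrow(tg), , drop = FALSE])
  tg <- tg / sqrt(rowSums(tg^2))
  if (any(abs(rowSums(tg * normals)) > 1e-3))
    stop("normals must be perpendicular to the local tangent")
  structure(list(points = points, normals = normals,
                 arc_spacing = mean(seglen)), class = "arch_curve")
}

#' @export
print.arch_curve <- function(x, ...) {
  cat(sprintf("<arch_curve> %d points, arc spacing %.3f voxels\n",
              nrow(x$points), x$arc_spacing))
  invisible(x)
}

#' Mean axial projection of a volume
#'
#' Pixel `(x, y)` is the mean over z of `X(x, y, z)` -- the mean intensity
#' projection along the axial direction used to expose the dental arch.
#'
#' @param volume a [voxel_volume].
#' @return numeric matrix (x by y).
#' @export
mean_axial_projection <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  rowMeans(volume$data, dims = 2)
}

#' Fit the dental arch curve on an axial projection
#'
#' Thresholds the projection at its Otsu level, takes the intensity-weighted
#' centroid of bright pixels in y for every supporting x column, fits a
#' weighted quartic polynomial `y = q(x)` through the centroids, and
#' resamples the fit to `n_points` points at equal arc length. Normals are
#' unit, perpendicular to the local tangent, and consistently oriented
#' buccally (away from the curve centroid).
#'
#' @param projection matrix from [mean_axial_projection()] (x by y).
#' @param n_points number of resampled curve points (the panoramic width).
#' @param degree polynomial degree of the fit (quartic by default: it
#'   captures molar flare that a parabola misses).
#' @param extend_px extrapolation of the fitted polynomial beyond the
#'   supported x range, in pixels per side, so the curve reaches the distal
#'   caps of the last molars where per-column support tapers off.
#' @return an [arch_curve] in 1-based voxel coordinates of the projection.
#' @export
fit_arch_curve <- function(projection, n_points = 320L, degree = 4L,
                           extend_px = 8) {
  thr <- otsu_threshold(projection)
  bright <- projection > thr
  nx <- nrow(projection)
  cx <- rep(NA_real_, nx); wx <- rep(0, nx)
  ys <- seq_len(ncol(projection))
  for (i in seq_len(nx)) {
    sel <- bright[i, ]
    if (!any(sel)) next
    wts <- projection[i, sel] - thr
    cx[i] <- sum(ys[sel] * wts) / sum(wts)
    wx[i] <- sum(wts)
  }
  sup <- which(!is.na(cx))
  if (length(sup) >= 5L) {
    # columns with marginal bright mass (clipped band ends) bias the fit
    sup <- sup[wx[sup] >= 0.2 * stats::median(wx[sup])]
  }
  if (length(sup) < 5L) stop("arch not found: fewer than 5 supporting columns")
  fit <- stats::lm(cx[sup] ~ poly(sup, degree, raw = TRUE), weights = wx[sup])
  # robust second pass: columns where the truncated ends of the bright band
  # bias the centroid show up as outliers against the first fit
  resid1 <- abs(stats::residuals(fit))
  keep <- resid1 <= pmax(2, 3 * stats::median(resid1))
  if (sum(keep) >= 5 && !all(keep)) {
    sup <- sup[keep]
    fit <- stats::lm(cx[sup] ~ poly(sup, degree, raw = TRUE),
                     weights = wx[sup])
  }
  xs <- seq(max(1, min(sup) - extend_px),
            min(nrow(projection), max(sup) + extend_px),
            length.out = 40L * length(sup))
  qy <- as.vector(cbind(1, stats::poly(xs, degree, raw = TRUE)) %*%
                    stats::coef(fit))
  # resample at equal arc length
  seg <- sqrt(diff(xs)^2 + diff(qy)^2)
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], length.out = n_points)
  px <- stats::approx(s, xs, xout = si)$y
  py <- stats::approx(s, qy, xout = si)$y
  pts <- cbind(px, py)
  tg <- diff(pts)
  tg <- rbind(tg, tg[nrow(tg), , drop = FALSE])
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- cbind(tg[, 2], -tg[, 1])
  cen <- colMeans(pts)
  flip <- rowSums(nrm * sweep(pts, 2, cen)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  arch_curve(pts, nrm)
}

#' Panoramic image along an arch curve
#'
#' `P(c, z)` is the mean of `2K + 1` samples of the volume taken at
#' `r(c) + t n(c)` for `t` in `-w..w` (step `w/K`), bilinearly interpolated
#' in the axial plane; out-of-grid samples are excluded from the mean. The
#' discrete mean replaces the band integral so panoramic intensities stay on
#' the input scale.
#'
#' @param volume a [voxel_volume].
#' @param curve an [arch_curve] in this volume's axial voxel coordinates.
#' @param w normal half-width in voxels (>= 1). The default 15 voxels
#'   corresponds to about 4.5 mm at 0.3 mm spacing, a typical crown depth
#'   half-extent.
#' @param K samples per half-width; defaults to `w` (1-voxel steps).
#' @return object of class `panoramic_image`: list with `data` (Nc x Nz
#'   matrix), `curve`, `w`, `K`.
#' @export
extract_panoramic <- function(volume, curve, w = 15, K = NULL) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(curve, "arch_curve"))
  if (w < 1) stop("w must be >= 1")
  K <- as.integer(K %||% max(1L, round(w)))
  d <- dim(volume$data)
  Nc <- nrow(curve$points); Nz <- d[3]
  acc <- matrix(0, Nc, Nz)
  cnt <- matrix(0, Nc, Nz)
  ts <- seq(-w, w, length.out = 2L * K + 1L)
  m <- matrix(volume$data, nrow = d[1] * d[2])  # (x,y) rows, z columns
  for (t in ts) {
    xi <- curve$points[, 1] + t * curve$normals[, 1]
    yi <- curve$points[, 2] + t * curve$normals[, 2]
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2]
    if (!any(ok)) next
    i0 <- clamp(floor(xi[ok]), 1, d[1] - 1L)
    j0 <- clamp(floor(yi[ok]), 1, d[2] - 1L)
    di <- xi[ok] - i0; dj <- yi[ok] - j0
    w00 <- (1 - di) * (1 - dj); w10 <- di * (1 - dj)
    w01 <- (1 - di) * dj;       w11 <- di * dj
    lin00 <- (j0 - 1L) * d[1] + i0
    samp <- w00 * m[lin00, , drop = FALSE] + w10 * m[lin00 + 1L, , drop = FALSE] +
      w01 * m[lin00 + d[1], , drop = FALSE] +
      w11 * m[lin00 + d[1] + 1L, , drop = FALSE]
    acc[ok, ] <- acc[ok, ] + samp
    cnt[ok, ] <- cnt[ok, ] + 1
  }
  if (all(cnt == 0)) stop("curve lies outside the volume grid for every t")
  P <- acc / ifelse(cnt > 0, cnt, NA)
  structure(list(data = P, curve = curve, w = w, K = K),
            class = "panoramic_image")
}

#' @export
print.panoramic_image <- function(x, ...) {
  cat(sprintf("<panoramic_image> %d x %d (arc x axial), w = %g voxels\n",
              nrow(x$data), ncol(x$data), x$w))
  invisible(x)
}

#' Project a 3D voxel point into panoramic coordinates
#'
#' `c` is the index (1-based) of the nearest curve point in the axial plane;
#' the axial coordinate passes through unchanged. Returns `NA` when the
#' planar distance to every curve point exceeds `w` -- the none-return is the
#' contract, not an error.
#'
#' @param point numeric length-3 (or n x 3 matrix) voxel coordinate(s).
#' @param curve an [arch_curve].
#' @param w planar distance cutoff in voxels.
#' @return matrix with columns `c`, `z` (NA rows where unprojectable).
#' @export
project_point_to_panoramic <- function(point, curve, w = 15) {
  p <- if (is.null(dim(point))) matrix(point, ncol = 3) else as.matrix(point)
  cp <- curve$points
  out <- matrix(NA_real_, nrow(p), 2, dimnames = list(NULL, c("c", "z")))
  for (i in seq_len(nrow(p))) {
    d2 <- (cp[, 1] - p[i, 1])^2 + (cp[, 2] - p[i, 2])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= w) out[i, ] <- c(j, p[i, 3])
  }
  out
}
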