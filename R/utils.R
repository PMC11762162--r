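# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Otsu threshold of a numeric image
#'
#' Histogram-based Otsu threshold on arbitrary real intensities (EBImage's
#' `otsu()` requires \[0,1\] grayscale, so intensities are binned here and the
#' between-class variance maximised directly).
#'
#' @param x numeric vector/matrix of intensities (non-finite values dropped).
#' @param nbins number of histogram bins.
#' @return threshold value; pixels `> threshold` form the bright class.
#' @keywords internal
#' @noRd
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  brk <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- (brk[-1] + brk[-length(brk)]) / 2
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sb <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  centers[which.max(sb)]
}

# Otsu applied to the bright tail only: first split background/foreground,
# then split the foreground again (bone vs enamel-level intensities).
bright_tail_otsu <- function(x) {
  t1 <- otsu_threshold(x)
  xb <- x[x > t1]
  if (length(xb) < 16 || diff(range(xb)) == 0) return(t1)
  otsu_threshold(xb)
}

# Bilinear interpolation of matrix `img` at real-valued (i, j) positions given
# in 1-based matrix coordinates. Out-of-grid samples return NA.
bilinear_sample <- function(img, i, j) {
  ni <- nrow(img); nj <- ncol(img)
  out <- rep(NA_real_, length(i))
  ok <- i >= 1 & i <= ni & j >= 1 & j <= nj
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]
  i0 <- clamp(floor(i), 1, ni - 1L); j0 <- clamp(floor(j), 1, nj - 1L)
  di <- i - i0; dj <- j - j0
  v00 <- img[cbind(i0, j0)];     v10 <- img[cbind(i0 + 1, j0)]
  v01 <- img[cbind(i0, j0 + 1)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - di) * (1 - dj) + v10 * di * (1 - dj) +
    v01 * (1 - di) * dj + v11 * di * dj
  out
}

# Trilinear interpolation of a 3D array at real-valued 1-based (i, j, k).
trilinear_sample <- function(arr, i, j, k) {
  d <- dim(arr)
  out <- rep(NA_real_, length(i))
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  if (!any(ok)) return(out)
  i <- i[ok]; j <- j[ok]; k <- k[ok]
  i0 <- clamp(floor(i), 1, d[1] - 1L)
  j0 <- clamp(floor(j), 1, d[2] - 1L)
  k0 <- clamp(floor(k), 1, d[3] - 1L)
  di <- i - i0; dj <- j - j0; dk <- k - k0
  val <- 0
  for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
    wgt <- (if (ci) di else 1 - di) * (if (cj) dj else 1 - dj) *
      (if (ck) dk else 1 - dk)
    val <- val + wgt * arr[cbind(i0 + ci, j0 + cj, k0 + ck)]
  }
  out[ok] <- val
  out
}

# 2x2 / 3x3 rotation helpers (degrees, counter-clockwise).
rot2 <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# Rotation about the x (lateral/frontal) axis.
rot3_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

# Rotation about the z (axial) axis.
rot3_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Local maxima of a 1D profile with topographic prominence. Returns a data
# frame of index/value/prominence for peaks with prominence >= min_prominence.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), value = numeric(),
                               prominence = numeric()))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  # plateaus: keep the first index of any flat top
  if (!length(idx)) return(data.frame(index = integer(), value = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(p) {
    v <- y[p]
    left <- y[seq_len(p - 1)]
    right <- y[seq.int(p + 1, n)]
    hl <- which(left >= v); hr <- which(right >= v)
    lmin <- if (!length(hl)) min(left)
      else if (max(hl) + 1 > p - 1) v
      else min(y[seq.int(max(hl) + 1, p - 1)])
    rmin <- if (!length(hr)) min(right)
      else if (min(hr) == 1) v
      else min(y[seq.int(p + 1, p + min(hr) - 1)])
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], value = y[idx[keep]], prominence = prom[keep])
}
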