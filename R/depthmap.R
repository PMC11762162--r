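#' Axial depth map
#'
#' A 2D grid of axial (z) coordinate values over the (x, y) plane, paired
#' with a validity mask for cells where no surface was seen. Depth values are
#' stored in the units declared by `units` ("mm" or "voxel"); `spacing` and
#' `origin` map grid cells to mm so 2D landmarks can be lifted to 3D.
#'
#' @param z numeric matrix of depth values (finite wherever valid).
#' @param valid logical matrix, same shape as `z`.
#' @param spacing mm per cell along (x, y).
#' @param origin mm position of the grid corner.
#' @param units units of the stored z values.
#' @return an object of class `depth_map`.
#' @export
depth_map <- function(z, valid = is.finite(z), spacing = c(1, 1),
                      origin = c(0, 0), units = c("mm", "voxel")) {
  units <- match.arg(units)
  if (!all(dim(z) == dim(valid))) stop("`z` and `valid` shapes differ")
  if (any(!is.finite(z[valid]))) stop("depth values non-finite where valid")
  structure(list(z = z, valid = valid, spacing = rep_len(spacing, 2L),
                 origin = rep_len(origin, 2L), units = units),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d cells (%.1f%% valid), %s units\n",
              nrow(x$z), ncol(x$z), 100 * mean(x$valid), x$units))
  invisible(x)
}

# Depth in `units` at the nearest valid cell within `radius` cells of the
# real-valued grid position (i, j); NA when no valid cell is in range.
depth_at <- function(depth, i, j, radius = 3L) {
  ni <- nrow(depth$z); nj <- ncol(depth$z)
  i0 <- round(i); j0 <- round(j)
  if (i0 < 1 - radius || i0 > ni + radius || j0 < 1 - radius ||
      j0 > nj + radius) return(NA_real_)
  ii <- max(1L, i0 - radius):min(ni, i0 + radius)
  jj <- max(1L, j0 - radius):min(nj, j0 + radius)
  sub <- depth$valid[ii, jj, drop = FALSE]
  if (!any(sub)) return(NA_real_)
  w <- which(sub, arr.ind = TRUE)
  d2 <- (ii[w[, 1]] - i)^2 + (jj[w[, 2]] - j)^2
  best <- w[which.min(d2), , drop = FALSE]
  depth$z[ii[best[1]], jj[best[2]]]
}

# Rasterize points (x, y, z in mm) into a max-z depth map on a grid of the
# given mm resolution.
rasterize_depth <- function(x, y, z, cell_mm, pad_mm = 1) {
  x0 <- min(x) - pad_mm; y0 <- min(y) - pad_mm
  ni <- ceiling((max(x) + pad_mm - x0) / cell_mm)
  nj <- ceiling((max(y) + pad_mm - y0) / cell_mm)
  i <- pmin(pmax(ceiling((x - x0) / cell_mm), 1L), ni)
  j <- pmin(pmax(ceiling((y - y0) / cell_mm), 1L), nj)
  zmat <- matrix(-Inf, ni, nj)
  lin <- (j - 1L) * ni + i
  ord <- order(z)  # later (larger z) writes win
  zmat[lin[ord]] <- z[ord]
  valid <- is.finite(zmat)
  zmat[!valid] <- NA_real_
  depth_map(zmat, valid, spacing = c(cell_mm, cell_mm), origin = c(x0, y0),
            units = "mm")
}
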