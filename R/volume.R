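#' Voxel volume container
#'
#' A 3D scalar intensity grid with physical spacing and origin. Axis semantics
#' are fixed throughout the package: the first array dimension is x (the
#' lateral, "frontal" axis), the second is y (the anterior--posterior slicing
#' axis along which sagittal-view slices are taken), and the third is z (the
#' axial, cranio-caudal axis). Intensities are Hounsfield-like arbitrary real
#' values. Internal indexing is zero-based half-open wherever coordinates are
#' reported in files; R arrays are addressed 1-based internally, and the voxel
#' with 1-based index `i` has physical center `origin + (i - 0.5) * spacing`.
#'
#' @param data numeric 3D array of intensities (finite).
#' @param spacing numeric length-3, mm per voxel along (x, y, z); positive.
#' @param origin numeric length-3, mm offset of the grid corner.
#' @return an object of class `voxel_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.3, 0.3, 0.3))
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive and finite")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensity grid contains non-finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm, origin (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Rectangular region of interest on a voxel grid
#'
#' Per-axis integer bounds, zero-based half-open: a voxel with zero-based
#' index `i` along an axis is inside when `low <= i < high`.
#'
#' @param x_lim,y_lim,z_lim integer length-2 `(low, high)` bounds per axis.
#' @return an object of class `region_of_interest`.
#' @examples
#' region_of_interest(c(0, 4), c(1, 3), c(0, 2))
#' @export
region_of_interest <- function(x_lim, y_lim, z_lim) {
  roi <- list(x = as.integer(x_lim), y = as.integer(y_lim),
              z = as.integer(z_lim))
  for (ax in c("x", "y", "z")) {
    b <- roi[[ax]]
    if (length(b) != 2L || anyNA(b) || b[1] >= b[2])
      stop(sprintf("roi bounds along %s must satisfy low < high", ax))
    if (b[1] < 0L) stop(sprintf("roi low bound along %s is negative", ax))
  }
  structure(roi, class = "region_of_interest")
}

#' Crop a voxel volume to a region of interest
#'
#' The output grid has the extents of the ROI and its origin is shifted by
#' the ROI low corner times the voxel spacing, so physical coordinates of
#' retained voxels are unchanged.
#'
#' @param volume a [voxel_volume].
#' @param roi a [region_of_interest] contained in the grid.
#' @return the cropped [voxel_volume].
#' @examples
#' v <- voxel_volume(array(seq_len(24), c(4, 3, 2)))
#' crop_volume(v, region_of_interest(c(1, 3), c(0, 2), c(0, 1)))
#' @export
crop_volume <- function(volume, roi) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(roi, "region_of_interest"))
  d <- dim(volume$data)
  hi <- c(roi$x[2], roi$y[2], roi$z[2])
  if (any(hi > d))
    stop(sprintf("roi exceeds the grid: high bounds (%s) vs dims (%s)",
                 paste(hi, collapse = ","), paste(d, collapse = ",")))
  lo <- c(roi$x[1], roi$y[1], roi$z[1])
  sub <- volume$data[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2],
                     (lo[3] + 1L):hi[3], drop = FALSE]
  voxel_volume(sub, spacing = volume$spacing,
               origin = volume$origin + lo * volume$spacing)
}

# physical mm center coordinates of 1-based voxel indices
voxel_center_mm <- function(volume, idx1) {
  sweep(sweep(idx1 - 0.5, 2, volume$spacing, "*"), 2, volume$origin, "+")
}
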