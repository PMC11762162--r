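#' Reference 2D slice segmenter (classical backend)
#'
#' A classical stand-in for a learned instance segmenter, usable for both
#' sagittal-view slices and panoramic images. The image is thresholded at
#' the tooth-enamel intensity level (bright-tail Otsu unless a fixed
#' threshold is configured), opened to remove specks, labeled into connected
#' components, and components whose height exceeds 1.5x the median component
#' height are split by distance-transform watershed. Any 2D segmenter with
#' the same signature (image -> list of binary masks) can be injected in its
#' place, so a learned model can replace the classical one without code
#' changes elsewhere.
#'
#' @param threshold fixed intensity threshold, or `NULL` for bright-tail
#'   Otsu (Otsu applied to the pixels above the global Otsu level).
#' @param min_pixels components smaller than this are discarded.
#' @param opening_radius radius (pixels) of the morphological opening brush.
#' @param split_factor components whose extent exceeds `split_factor` times
#'   the median extent along the split axis are watershed-split.
#' @param split_axis which extent triggers splitting: `"height"` (the z
#'   extent; right for sagittal-view slices, where a closed bite fuses an
#'   upper and a lower tooth vertically) or `"both"` (also the lateral
#'   extent; right for panoramic images, where neighboring teeth fuse along
#'   the arch).
#' @param ws_ext watershed peak-neighborhood radius in pixels.
#' @param max_height_px,max_width_px absolute extent caps: a component
#'   taller/wider than this is always watershed-split (`NULL` disables).
#'   The relative rule is degenerate when every component in a slice is a
#'   fused pair (a closed bite fuses all of them), so the pipeline also caps
#'   extents at anatomically plausible single-crown sizes.
#' @return a segmenter: `function(image)` returning a list of logical mask
#'   matrices (disjoint).
#' @export
slice_segmenter <- function(threshold = NULL, min_pixels = 12L,
                            opening_radius = 1L, split_factor = 1.5,
                            split_axis = c("height", "both"), ws_ext = 1L,
                            max_height_px = NULL, max_width_px = NULL) {
  split_axis <- match.arg(split_axis)
  function(image) {
    thr <- threshold %||% bright_tail_otsu(image)
    bw <- image > thr
    if (!any(bw)) return(list())
    if (opening_radius > 0) {
      brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
      bw <- EBImage::opening(bw, brush) > 0
    }
    if (!any(bw)) return(list())
    labels <- EBImage::bwlabel(bw)
    masks <- component_masks(labels, min_pixels)
    if (!length(masks)) return(list())
    heights <- vapply(masks, mask_height, numeric(1))
    med_h <- stats::median(heights)
    widths <- vapply(masks, mask_width, numeric(1))
    med_w <- stats::median(widths)
    out <- list()
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      oversize <- (med_h > 0 && mask_height(m) > split_factor * med_h) ||
        (split_axis == "both" && med_w > 0 &&
           mask_width(m) > split_factor * med_w) ||
        (!is.null(max_height_px) && mask_height(m) > max_height_px) ||
        (!is.null(max_width_px) && mask_width(m) > max_width_px)
      if (oversize) {
        out <- c(out, watershed_split(m, min_pixels, ws_ext))
      } else out <- c(out, list(m))
    }
    out
  }
}

mask_height <- function(m) {
  cols <- which(colSums(m) > 0)
  if (!length(cols)) 0 else diff(range(cols)) + 1
}

mask_width <- function(m) {
  rws <- which(rowSums(m) > 0)
  if (!length(rws)) 0 else diff(range(rws)) + 1
}

component_masks <- function(labels, min_pixels = 1L) {
  n <- max(labels)
  out <- list()
  for (i in seq_len(n)) {
    m <- labels == i
    if (sum(m) >= min_pixels) out[[length(out) + 1L]] <- m
  }
  out
}

# split one oversized mask by watershed on its distance transform
watershed_split <- function(m, min_pixels = 1L, ws_ext = 1L) {
  dm <- EBImage::distmap(EBImage::Image(m * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = ws_ext)
  ws <- as.integer(ws) * as.integer(m)
  dim(ws) <- dim(m)
  parts <- component_masks(ws, min_pixels)
  if (length(parts)) parts else list(m)
}

#' Representative point of a slice-mask bounding box
#'
#' The center of the detected box `(x, z, h, w)` in a sagittal-view slice
#' `s`: `(x + w/2, s, z + h/2)` with width along x and height along z (the
#' only self-consistent reading of the box convention). Real-valued.
#'
#' @param box numeric: `x`, `z` (zero-based low corner), `h` (extent along
#'   z), `w` (extent along x).
#' @param s slice index along the y axis.
#' @return numeric length-3 voxel coordinate `(x, y, z)`.
#' @export
representative_point <- function(box, s) {
  box <- as.numeric(box)
  if (length(box) != 4L || box[3] <= 0 || box[4] <= 0)
    stop("box must be (x, z, h, w) with positive extents")
  c(box[1] + box[4] / 2, s, box[2] + box[3] / 2)
}

# zero-based bounding box (x, z, h, w) of a slice mask (x rows, z cols)
mask_box <- function(m) {
  rws <- which(rowSums(m) > 0); cls <- which(colSums(m) > 0)
  c(x = min(rws) - 1, z = min(cls) - 1,
    h = diff(range(cls)) + 1, w = diff(range(rws)) + 1)
}

#' Split panoramic tooth masks into upper and lower sets
#'
#' Segments teeth on the panoramic image, clusters mask centroids into two
#' groups by axial position (2-means on z), fits the least-squares boundary
#' line `z = a c + b` through the midpoints of vertically adjacent
#' upper/lower centroid pairs, and assigns each mask to the side of the line
#' its centroid falls on.
#'
#' @param pano a `panoramic_image`.
#' @param segmenter a 2D segmenter (see [slice_segmenter()]).
#' @return list of class `panoramic_tooth_masks`: `upper`, `lower` (lists of
#'   logical masks in panoramic (c, z) coordinates), `line` (`c(a, b)`),
#'   `upper_is_low_z` (orientation flag).
#' @export
split_panoramic_masks <- function(pano,
                                  segmenter = slice_segmenter(
                                    split_axis = "both", ws_ext = 5L)) {
  stopifnot(inherits(pano, "panoramic_image"))
  img <- pano$data
  img[is.na(img)] <- min(img, na.rm = TRUE)
  masks <- segmenter(img)
  if (length(masks) < 2L)
    stop("cannot establish jaw boundary: fewer than 2 panoramic masks")
  cen <- t(vapply(masks, mask_centroid, numeric(2)))
  if (nrow(cen) == 2L) {
    # kmeans needs n > k; two masks split by z order directly
    cluster <- order(order(cen[, 2]))
    centers <- cen[order(cen[, 2]), 2]
  } else {
    km <- stats::kmeans(cen[, 2], centers = 2L, nstart = 5L)
    cluster <- km$cluster
    centers <- as.numeric(km$centers)
  }
  if (any(tabulate(cluster, 2L) == 0L))
    stop("cannot establish jaw boundary: one z cluster is empty")
  lo <- which.min(centers)             # low z cluster = lower jaw (z is up)
  g_lo <- cluster == lo
  # midpoints of adjacent pairs: nearest other-group centroid in c
  mids <- NULL
  for (i in which(g_lo)) {
    j <- which(!g_lo)[which.min(abs(cen[!g_lo, 1] - cen[i, 1]))]
    mids <- rbind(mids, (cen[i, ] + cen[j, ]) / 2)
  }
  line <- if (nrow(mids) >= 2L && stats::sd(mids[, 1]) > 0) {
    stats::coef(stats::lm(mids[, 2] ~ mids[, 1]))[c(2, 1)]
  } else c(0, mean(mids[, 2]))
  pred <- line[1] * cen[, 1] + line[2]
  upper_sel <- cen[, 2] > pred
  if (!any(upper_sel) || all(upper_sel))
    stop("cannot establish jaw boundary: boundary line does not separate masks")
  structure(list(upper = masks[upper_sel], lower = masks[!upper_sel],
                 line = c(a = unname(line[1]), b = unname(line[2]))),
            class = "panoramic_tooth_masks")
}

mask_centroid <- function(m) {
  w <- which(m, arr.ind = TRUE)
  c(mean(w[, 1]), mean(w[, 2]))
}

#' Assign sagittal slice masks to the upper or lower jaw
#'
#' Segments every slice along the y axis with the supplied segmenter,
#' projects each slice-mask's representative point into the panoramic frame,
#' and ORs the mask's voxels into the upper or lower binary volume according
#' to which panoramic tooth mask the projected pixel falls in. A projected
#' point in neither mask set is attached to the nearest mask within a pixel
#' tolerance `tau`; otherwise the slice mask is counted unassigned (reported,
#' not fatal).
#'
#' @param volume the [voxel_volume] the slices come from.
#' @param pano_masks a `panoramic_tooth_masks` from [split_panoramic_masks()].
#' @param curve the [arch_curve] used for the panoramic image.
#' @param w panoramic projection half-width (voxels).
#' @param segmenter the 2D slice segmenter.
#' @param tau nearest-mask membership tolerance in panoramic pixels.
#' @return list of class `jaw_assignment`: `upper`, `lower` (logical arrays),
#'   `n_masks`, `n_unassigned`.
#' @export
assign_jaws <- function(volume, pano_masks, curve, w = 15,
                        segmenter = slice_segmenter(), tau = 3) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(pano_masks, "panoramic_tooth_masks"))
  d <- dim(volume$data)
  upper <- array(FALSE, d); lower <- array(FALSE, d)
  n_masks <- 0L; n_unassigned <- 0L
  up_idx <- lapply(pano_masks$upper, which)
  lo_idx <- lapply(pano_masks$lower, which)
  pd <- dim(pano_masks$upper[[1]])
  up_any <- Reduce(`|`, pano_masks$upper)
  lo_any <- Reduce(`|`, pano_masks$lower)
  up_pts <- which(up_any, arr.ind = TRUE)
  lo_pts <- which(lo_any, arr.ind = TRUE)
  for (s in seq_len(d[2])) {
    slice <- volume$data[, s, ]
    masks <- segmenter(slice)
    for (m in masks) {
      n_masks <- n_masks + 1L
      p <- representative_point(mask_box(m), s - 1)  # zero-based box -> 0-based pt
      p1 <- p + c(0.5, 1, 0.5)  # to 1-based continuous voxel coords
      cz <- project_point_to_panoramic(p1, curve, w)
      assigned <- NA_character_
      if (!is.na(cz[1, 1])) {
        ci <- as.integer(round(cz[1, 1]))
        zi <- as.integer(round(cz[1, 2]))
        if (ci >= 1 && ci <= pd[1] && zi >= 1 && zi <= pd[2]) {
          if (up_any[ci, zi]) assigned <- "upper"
          else if (lo_any[ci, zi]) assigned <- "lower"
          else {
            du <- min(sqrt((up_pts[, 1] - ci)^2 + (up_pts[, 2] - zi)^2))
            dl <- min(sqrt((lo_pts[, 1] - ci)^2 + (lo_pts[, 2] - zi)^2))
            if (min(du, dl) <= tau)
              assigned <- if (du <= dl) "upper" else "lower"
          }
        }
      }
      if (is.na(assigned)) {
        n_unassigned <- n_unassigned + 1L
      } else {
        idx <- which(m, arr.ind = TRUE)
        tgt <- cbind(idx[, 1], s, idx[, 2])
        if (assigned == "upper") upper[tgt] <- TRUE else lower[tgt] <- TRUE
      }
    }
  }
  if (any(upper & lower)) stop("internal error: jaws overlap") # hard invariant
  structure(list(upper = upper, lower = lower, n_masks = n_masks,
                 n_unassigned = n_unassigned), class = "jaw_assignment")
}

#' @export
print.jaw_assignment <- function(x, ...) {
  cat(sprintf("<jaw_assignment> %d slice masks (%d unassigned); upper %d vox, lower %d vox\n",
              x$n_masks, x$n_unassigned, sum(x$upper), sum(x$lower)))
  invisible(x)
}
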