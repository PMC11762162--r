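#' Align a jaw volume by the mandibular inclination angle
#'
#' Resamples the volume after rotation by `-alpha` about the frontal (x)
#' axis with trilinear interpolation, so the occlusal plane becomes parallel
#' to the axial plane before projection. `alpha = 0` is the identity. When
#' `alpha = NULL` the angle is estimated as the tilt of the principal plane
#' of the teeth-level voxels relative to the axial plane.
#'
#' @param volume a [voxel_volume].
#' @param alpha rotation angle in degrees, or `NULL` to estimate.
#' @param threshold teeth-intensity threshold for the fallback estimator
#'   (bright-tail Otsu when `NULL`).
#' @param jaw occlusal-surface orientation hint passed to the estimator.
#' @return the aligned [voxel_volume]; the applied angle is attached as
#'   attribute `"alpha_deg"`.
#' @export
align_jaw <- function(volume, alpha = NULL, threshold = NULL,
                      jaw = c("none", "upper", "lower")) {
  stopifnot(inherits(volume, "voxel_volume"))
  jaw <- match.arg(jaw)
  if (is.null(alpha)) alpha <- estimate_inclination(volume, threshold, jaw)
  if (!is.finite(alpha)) stop("alpha must be finite")
  if (abs(alpha) > 60) stop("implausible inclination: |alpha| > 60 degrees")
  if (alpha == 0) {
    out <- volume
    attr(out, "alpha_deg") <- 0
    return(out)
  }
  d <- dim(volume$data)
  R <- rot3_x(-alpha)
  ctr <- (d + 1) / 2
  out <- array(0, d)
  # inverse map, slab by slab to bound memory
  Rt <- t(R)
  ij <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  # physical anisotropy: rotate in mm space
  spz <- volume$spacing
  for (k in seq_len(d[3])) {
    p <- cbind(ij[, 1], ij[, 2], k)
    pm <- sweep(sweep(p, 2, ctr), 2, spz, "*")
    q <- pm %*% R
    q <- sweep(sweep(q, 2, spz, "/"), 2, ctr, "+")
    vals <- trilinear_sample(volume$data, q[, 1], q[, 2], q[, 3])
    vals[is.na(vals)] <- 0
    out[, , k] <- vals
  }
  res <- voxel_volume(out, spacing = volume$spacing, origin = volume$origin)
  attr(res, "alpha_deg") <- alpha
  res
}

# Inclination of the occlusal plane vs the axial plane, as a rotation about
# the x axis (degrees). The plane is fit to the occlusal surface -- the
# z extreme of the teeth voxels facing the bite plane per (x, y) column --
# rather than to all teeth voxels: crown heights vary by tooth type, which
# tilts the voxel-cloud principal plane even in a perfectly level jaw.
estimate_inclination <- function(volume, threshold = NULL,
                                 jaw = c("none", "upper", "lower")) {
  jaw <- match.arg(jaw)
  thr <- threshold %||% bright_tail_otsu(volume$data)
  idx <- which(volume$data > thr, arr.ind = TRUE)
  if (nrow(idx) < 100) stop("too few teeth-level voxels to estimate alpha")
  col <- (idx[, 2] - 1) * dim(volume$data)[1] + idx[, 1]
  zmm <- idx[, 3] * volume$spacing[3]
  occl_max <- jaw == "lower" ||
    (jaw == "none" && stats::median(idx[, 3]) < (dim(volume$data)[3] + 1) / 2)
  zocc <- if (occl_max) tapply(zmm, col, max) else tapply(zmm, col, min)
  cols <- as.integer(names(zocc))
  ymm <- ((cols - 1) %/% dim(volume$data)[1] + 1) * volume$spacing[2]
  fit <- stats::lm(as.numeric(zocc) ~ ymm)
  unname(atan(stats::coef(fit)[2]) * 180 / pi)
}

#' Maximum intensity projection of a jaw volume
#'
#' Pixel `(x, y)` is the maximum over z; the paired depth map records the
#' smallest z index attaining the maximum (after any orientation flip, so
#' depth is always occlusal-surface-first: for the lower jaw -- whose
#' occlusal surfaces face up -- the volume is z-flipped before projection and
#' the flip is recorded in the result).
#'
#' @param volume a [voxel_volume] (typically masked to one jaw).
#' @param jaw `"upper"`, `"lower"` or `"none"`; `"lower"` flips z so the
#'   occlusal surface is encountered first.
#' @return object of class `mip_image`: `data` (x by y matrix), `depth`
#'   (a [depth_map] in voxel units, z indices zero-based), `jaw`,
#'   `flipped_z`, `spacing`.
#' @export
compute_mip <- function(volume, jaw = c("none", "upper", "lower")) {
  stopifnot(inherits(volume, "voxel_volume"))
  jaw <- match.arg(jaw)
  arr <- volume$data
  flipped <- jaw == "lower"
  if (flipped) arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1] * d[2])
  amax_col <- max.col(m, ties.method = "first")
  mip <- matrix(m[cbind(seq_along(amax_col), amax_col)], d[1], d[2])
  amax <- matrix(amax_col, d[1], d[2])
  dm <- depth_map(amax - 1, valid = matrix(TRUE, d[1], d[2]),
                  spacing = volume$spacing[1:2], origin = c(0, 0),
                  units = "voxel")
  structure(list(data = mip, depth = dm, jaw = jaw, flipped_z = flipped,
                 spacing = volume$spacing),
            class = "mip_image")
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image> %d x %d, jaw %s%s\n", nrow(x$data), ncol(x$data),
              x$jaw, if (x$flipped_z) " (z flipped)" else ""))
  invisible(x)
}

#' Detect individual teeth on a MIP or depth map
#'
#' The reference detector thresholds the image (bright-tail Otsu unless
#' configured), then splits fused teeth by distance-transform watershed with
#' a minimum peak separation, and reports for every detection its binary
#' mask, bounding box and box-center representative point.
#'
#' @param mip a `mip_image`, or any numeric matrix (a scan-derived depth map
#'   image may stand in for the MIP).
#' @param threshold fixed threshold or `NULL` for bright-tail Otsu.
#' @param min_spacing_mm minimum watershed peak separation in mm.
#' @param min_area_mm2 detections smaller than this are dropped.
#' @param spacing mm per pixel (taken from the `mip_image` when available).
#' @return list of class `tooth_detections`: `labels` (integer matrix),
#'   `detections` (tibble: `id`, zero-based box `x0`, `y0`, `w`, `h`,
#'   center `cx`, `cy` in 1-based pixel coordinates, `area`).
#' @export
detect_teeth_on_mip <- function(mip, threshold = NULL, min_spacing_mm = 3.5,
                                min_area_mm2 = 6, spacing = NULL) {
  img <- if (inherits(mip, "mip_image")) mip$data else as.matrix(mip)
  spacing <- spacing %||%
    (if (inherits(mip, "mip_image")) mip$spacing[1:2] else c(1, 1))
  thr <- threshold %||% bright_tail_otsu(img)
  fg <- img > thr
  if (!any(fg)) stop("no teeth on MIP: empty foreground")
  fg <- EBImage::opening(fg, EBImage::makeBrush(3, "disc")) > 0
  if (!any(fg)) stop("no teeth on MIP: foreground vanished after opening")
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ext <- max(1L, round(min_spacing_mm / mean(spacing) / 2))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  labels <- as.integer(ws) * as.integer(fg)
  dim(labels) <- dim(fg)
  min_px <- max(4L, round(min_area_mm2 / prod(spacing)))
  rows <- list()
  keep <- 0L
  out_labels <- array(0L, dim(labels))
  for (i in seq_len(max(labels))) {
    sel <- labels == i
    n <- sum(sel)
    if (n < min_px) next
    keep <- keep + 1L
    w <- which(sel, arr.ind = TRUE)
    x0 <- min(w[, 1]) - 1L; y0 <- min(w[, 2]) - 1L
    bw <- diff(range(w[, 1])) + 1L; bh <- diff(range(w[, 2])) + 1L
    out_labels[sel] <- keep
    # Box center: (x0 + w/2, y0 + h/2) in zero-based continuous coords;
    # +0.5 converts to 1-based pixel-center coordinates.
    rows[[keep]] <- tibble::tibble(
      id = keep, x0 = x0, y0 = y0, w = bw, h = bh,
      cx = x0 + bw / 2 + 0.5, cy = y0 + bh / 2 + 0.5, area = n)
  }
  if (!keep) stop("no teeth on MIP: all components below minimum area")
  structure(list(labels = out_labels, detections = dplyr::bind_rows(rows),
                 spacing = spacing),
            class = "tooth_detections")
}

#' @export
print.tooth_detections <- function(x, ...) {
  cat(sprintf("<tooth_detections> %d teeth\n", nrow(x$detections)))
  print(x$detections, ...)
  invisible(x)
}

#' Extract the outer jaw profile from a MIP
#'
#' Morphological closing bridges inter-tooth gaps; the outer (buccal /
#' anterior) border of the closed foreground is traced as an open curve
#' between the two most-distal foreground points, ordered from the left
#' distal end to the right distal end; the centroid is the mean of the
#' boundary points.
#'
#' @param mip a `mip_image` or numeric matrix.
#' @param threshold foreground threshold (`NULL`: bright-tail Otsu).
#' @param closing_mm closing brush diameter in mm.
#' @param spacing mm per pixel when `mip` is a bare matrix.
#' @return object of class `jaw_profile`: `boundary` (n x 2 matrix of
#'   1-based pixel coordinates), `centroid`, `arc` (cumulative arc length),
#'   `spacing`; midline fields are filled by [estimate_midline()].
#' @export
extract_jaw_profile <- function(mip, threshold = NULL, closing_mm = 3,
                                spacing = NULL) {
  img <- if (inherits(mip, "mip_image")) mip$data else as.matrix(mip)
  spacing <- spacing %||%
    (if (inherits(mip, "mip_image")) mip$spacing[1:2] else c(1, 1))
  thr <- threshold %||% bright_tail_otsu(img)
  fg <- img > thr
  if (sum(colSums(fg) > 0) < 3 || sum(rowSums(fg) > 0) < 3)
    stop("arch profile not found: foreground spans fewer than 3 columns")
  br <- EBImage::makeBrush(2L * max(1L, round(closing_mm / mean(spacing) / 2)) + 1L,
                           "disc")
  fg <- EBImage::closing(fg, br) > 0
  fg <- EBImage::fillHull(EBImage::bwlabel(fg)) > 0
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(as.integer(lab))
  fg <- lab == which.max(sizes)
  oc <- EBImage::ocontour(EBImage::Image(fg * 1))[[1]] + 1  # 1-based
  # two most-distal (max y) contour points, one per lateral half
  xc <- mean(oc[, 1])
  left <- oc[, 1] < xc
  i_l <- which(left)[which.max(oc[left, 2])]
  i_r <- which(!left)[which.max(oc[!left, 2])]
  n <- nrow(oc)
  path1 <- if (i_l <= i_r) i_l:i_r else c(i_l:n, 1:i_r)
  path2 <- setdiff_path(n, path1)
  cen_all <- colMeans(oc)
  d1 <- mean(sqrt(rowSums(sweep(oc[path1, , drop = FALSE], 2, cen_all)^2)))
  d2 <- mean(sqrt(rowSums(sweep(oc[path2, , drop = FALSE], 2, cen_all)^2)))
  outer <- if (d1 >= d2) oc[path1, , drop = FALSE] else oc[path2, , drop = FALSE]
  # orient from left distal end to right distal end
  if (outer[1, 1] > outer[nrow(outer), 1]) outer <- outer[rev(seq_len(nrow(outer))), ]
  arc <- c(0, cumsum(sqrt(rowSums(diff(outer)^2))))
  # smooth tangents: the raw contour scallops around each crown bulge, so a
  # local finite difference misestimates the arch direction by 10 degrees or
  # more; a low-df arc-length spline averages the scallops out
  n <- nrow(outer)
  tangents <- matrix(NA_real_, n, 2)
  smooth <- NULL
  if (n >= 10) {
    # The traced boundary hooks around the distal cap of each last molar;
    # the splines are fit on the central arc range only, and the reference
    # polyline is continued by straight extrapolation along the trimmed
    # tangents: beyond the last contact the arch is ending and a linear
    # continuation keeps distal-cap arcs monotone.
    a0 <- 0.06 * max(arc); a1 <- 0.94 * max(arc)
    core <- arc >= a0 & arc <= a1
    if (sum(core) < 10) core <- rep(TRUE, n)
    df <- max(4, min(10, floor(sum(core) / 15)))
    fx <- stats::smooth.spline(arc[core], outer[core, 1], df = df)
    fy <- stats::smooth.spline(arc[core], outer[core, 2], df = df)
    dx <- stats::predict(fx, arc, deriv = 1)$y
    dy <- stats::predict(fy, arc, deriv = 1)$y
    nr <- sqrt(dx^2 + dy^2)
    tangents <- cbind(dx / nr, dy / nr)
    sg <- seq(min(arc[core]), max(arc[core]), by = 0.5)
    sx <- stats::predict(fx, sg)$y; sy <- stats::predict(fy, sg)$y
    sdx <- stats::predict(fx, sg, deriv = 1)$y
    sdy <- stats::predict(fy, sg, deriv = 1)$y
    snr <- sqrt(sdx^2 + sdy^2)
    sdx <- sdx / snr; sdy <- sdy / snr
    ext <- seq(0.5, 40, by = 0.5)
    m <- length(sg)
    pts <- rbind(
      cbind(sx[1] - rev(ext) * sdx[1], sy[1] - rev(ext) * sdy[1]),
      cbind(sx, sy),
      cbind(sx[m] + ext * sdx[m], sy[m] + ext * sdy[m]))
    tgs <- rbind(
      matrix(c(sdx[1], sdy[1]), length(ext), 2, byrow = TRUE),
      cbind(sdx, sdy),
      matrix(c(sdx[m], sdy[m]), length(ext), 2, byrow = TRUE))
    arcs <- c(sg[1] - rev(ext), sg, sg[m] + ext)
    smooth <- list(points = pts, arc = arcs, tangents = tgs)
  } else {
    tg <- diff(outer); tg <- rbind(tg, tg[nrow(tg), , drop = FALSE])
    tangents <- tg / sqrt(rowSums(tg^2))
  }
  structure(list(boundary = outer, centroid = colMeans(outer), arc = arc,
                 tangents = tangents, smooth = smooth, spacing = spacing,
                 mask = fg, p_mid = NULL, mid_index = NULL, axis = NULL),
            class = "jaw_profile")
}

setdiff_path <- function(n, path1) {
  a <- path1[length(path1)]; b <- path1[1]
  if (a <= b) a:b else c(a:n, 1:b)
}

#' @export
print.jaw_profile <- function(x, ...) {
  cat(sprintf("<jaw_profile> %d boundary points, centroid (%.1f, %.1f)%s\n",
              nrow(x$boundary), x$centroid[1], x$centroid[2],
              if (!is.null(x$p_mid)) sprintf(", midline (%.1f, %.1f)",
                                             x$p_mid[1], x$p_mid[2]) else ""))
  invisible(x)
}

#' Adaptive midline from the jaw profile
#'
#' Restricts candidates to the anterior (middle) third of the boundary arc
#' length, finds the maximum distance to the boundary centroid within it,
#' keeps the contiguous run of points whose distance is within `delta_d` of
#' that maximum, and returns their coordinate mean as the midline point. The
#' midline axis is the unit vector from the midline point through the
#' centroid. With `mode = "fixed"` the midline is instead the boundary point
#' at the centroid's column with a fixed image-vertical axis -- the
#' non-adaptive baseline that the adaptive estimator is designed to replace.
#'
#' @param profile a `jaw_profile`.
#' @param delta_d distance slack in pixels defining the near-tie run.
#' @param mode `"adaptive"` or `"fixed"`.
#' @return the profile with `p_mid`, `mid_index` and `axis` filled.
#' @export
estimate_midline <- function(profile, delta_d = 2, mode = c("adaptive", "fixed")) {
  stopifnot(inherits(profile, "jaw_profile"))
  mode <- match.arg(mode)
  b <- profile$boundary
  if (nrow(b) < 3) stop("boundary has fewer than 3 points")
  if (mode == "fixed") {
    # Non-adaptive baseline: the midline is anchored to the image frame
    # (the central column of the projection with an image-vertical axis),
    # so any deviation between the dentition and the scanner coordinate
    # frame -- head rotation or lateral displacement -- shifts teeth across
    # it. This is the behavior the adaptive estimator replaces.
    cx <- (nrow(profile$mask) + 1) / 2
    cand <- which(abs(b[, 1] - cx) <= 1)
    i <- if (length(cand)) cand[which.min(b[cand, 2])]
         else which.min(abs(b[, 1] - cx))
    profile$p_mid <- b[i, ]
    profile$mid_index <- i
    profile$axis <- c(0, 1)
    return(profile)
  }
  arc <- profile$arc
  total <- arc[length(arc)]
  sel <- which(arc >= total / 3 & arc <= 2 * total / 3)
  if (length(sel) < 1) sel <- seq_len(nrow(b))
  d <- sqrt(rowSums(sweep(b[sel, , drop = FALSE], 2, profile$centroid)^2))
  dmax <- max(d)
  qual <- which(d >= dmax - delta_d)
  run <- sel[min(qual):max(qual)]
  p_mid <- colMeans(b[run, , drop = FALSE])
  ax <- profile$centroid - p_mid
  profile$p_mid <- p_mid
  profile$mid_index <- round(mean(range(run)))
  profile$axis <- ax / sqrt(sum(ax^2))
  profile
}

#' Assign FDI-style numbers 1--6 per side
#'
#' Each detection is signed left/right by the side of the midline axis its
#' center falls on; within a side, detections are ordered by the arc-length
#' position of their projection onto the arch boundary, nearest to the
#' midline first, and numbered 1..6 in that order. More than 6 detections on
#' a side leaves the extras flagged unnumbered; fewer than 6 numbers what is
#' there and notes the shortfall.
#'
#' @param detections a `tooth_detections`.
#' @param profile a `jaw_profile` with the midline estimated.
#' @return the `tooth_detections` with `side` ("L"/"R"), `pos` (1..6 or NA)
#'   and `flag` columns added to the tibble.
#' @export
assign_fdi <- function(detections, profile) {
  stopifnot(inherits(detections, "tooth_detections"),
            inherits(profile, "jaw_profile"))
  if (is.null(profile$p_mid)) stop("midline not estimated")
  det <- detections$detections
  b <- profile$boundary
  ax <- profile$axis
  # arc position of the midline point
  mid_arc <- profile$arc[clamp(profile$mid_index %||%
                                 which.min(rowSums(sweep(b, 2, profile$p_mid)^2)),
                               1, nrow(b))]
  rel <- cbind(det$cx - profile$p_mid[1], det$cy - profile$p_mid[2])
  cross <- ax[1] * rel[, 2] - ax[2] * rel[, 1]
  # axis points posterior (midline -> centroid); positive cross = +x side.
  det$side <- ifelse(cross < 0, "R", "L")
  near_i <- vapply(seq_len(nrow(det)), function(i) {
    which.min((b[, 1] - det$cx[i])^2 + (b[, 2] - det$cy[i])^2)
  }, integer(1))
  det$arc_pos <- profile$arc[near_i] - mid_arc
  det$pos <- NA_integer_
  det$flag <- ""
  for (sd in c("L", "R")) {
    ii <- which(det$side == sd)
    ord <- ii[order(abs(det$arc_pos[ii]))]
    k <- seq_along(ord)
    det$pos[ord[k <= 6]] <- k[k <= 6]
    if (length(ord) > 6) det$flag[ord[k > 6]] <- "unnumbered_extra"
    if (length(ord) < 6 && length(ord) > 0)
      det$flag[ord] <- paste0(det$flag[ord],
                              ifelse(nzchar(det$flag[ord]), ";", ""),
                              "side_shortfall")
  }
  detections$detections <- det
  detections$profile <- profile
  detections
}

#' Run detection, profile, midline and numbering on a scan depth map
#'
#' The axial depth map converted from the teeth section of a scan stands in
#' for the MIP: the detection, jaw-profile, midline and numbering chain runs
#' unchanged on the depth image (valid cells are foreground).
#'
#' @param depth a [depth_map] in mm units (from [teeth_cloud_and_depthmap()]).
#' @param min_spacing_mm,delta_d_mm,midline_mode tuning as in the MIP path.
#' @return a numbered `tooth_detections` (with the profile attached).
#' @export
identify_from_depthmap <- function(depth, min_spacing_mm = 3.5,
                                   delta_d_mm = 0.6,
                                   midline_mode = "adaptive") {
  stopifnot(inherits(depth, "depth_map"))
  if (!any(depth$valid)) stop("no teeth on MIP: empty depth map")
  img <- depth$z
  zmin <- min(img[depth$valid])
  img[!depth$valid] <- zmin - 1
  img <- img - (zmin - 1)      # background 0, surfaces positive
  thr0 <- 0.5 * min(img[depth$valid])
  det <- detect_teeth_on_mip(img, threshold = thr0,
                             min_spacing_mm = min_spacing_mm,
                             spacing = depth$spacing)
  prof <- extract_jaw_profile(img, threshold = thr0, spacing = depth$spacing)
  prof <- estimate_midline(prof, delta_d = delta_d_mm / mean(depth$spacing),
                           mode = midline_mode)
  assign_fdi(det, prof)
}
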