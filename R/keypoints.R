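#' Crop a per-tooth region of interest
#'
#' Crops the detection box dilated by a margin out of the MIP (or depth)
#' image, clipped to the image, and attaches the local mesio-distal axis:
#' the tangent of the arch boundary at the tooth's nearest boundary point,
#' oriented toward increasing boundary arc length.
#'
#' @param image numeric matrix (MIP data or depth image) the detections were
#'   made on.
#' @param detections a numbered `tooth_detections`.
#' @param id detection id to crop.
#' @param profile the `jaw_profile` (with midline) for the axis.
#' @param margin_mm dilation margin in mm.
#' @param spacing mm per pixel.
#' @return object of class `tooth_roi`: `img`, `mask` (this tooth's pixels),
#'   `offset` (zero-based global offset of the crop), `axis` (unit 2D,
#'   mesio-distal), `det` (the detection row), `spacing`.
#' @export
crop_tooth_roi <- function(image, detections, id, profile, margin_mm = 3,
                           spacing = c(1, 1)) {
  det <- detections$detections
  row <- det[det$id == id, ]
  if (nrow(row) != 1) stop("unknown detection id")
  mg <- round(margin_mm / mean(spacing))
  d <- dim(image)
  x1 <- max(1L, row$x0 + 1L - mg); x2 <- min(d[1], row$x0 + row$w + mg)
  y1 <- max(1L, row$y0 + 1L - mg); y2 <- min(d[2], row$y0 + row$h + mg)
  if (x1 > d[1] || y1 > d[2] || x2 < 1 || y2 < 1)
    stop("tooth crop falls outside the image")
  b <- profile$boundary
  ni <- which.min((b[, 1] - row$cx)^2 + (b[, 2] - row$cy)^2)
  tg <- profile$tangents[ni, ]
  if (anyNA(tg)) {
    lo <- max(1L, ni - 3L); hi <- min(nrow(b), ni + 3L)
    tg <- b[hi, ] - b[lo, ]
    tg <- tg / sqrt(sum(tg^2))
  }
  structure(list(
    img = image[x1:x2, y1:y2, drop = FALSE],
    mask = detections$labels[x1:x2, y1:y2, drop = FALSE] == id,
    fg = detections$labels[x1:x2, y1:y2, drop = FALSE] > 0,
    offset = c(x1 - 1L, y1 - 1L), axis = tg, det = row,
    profile = profile, spacing = spacing), class = "tooth_roi")
}

# pixels at the extreme of the mask along +/- axis; returns the mean of the
# near-tie extreme pixels (midpoint of an edge for a box mask)
extreme_point <- function(mask, axis, end = c("min", "max"), tie_px = 0.6) {
  end <- match.arg(end)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 3) stop("degenerate tooth mask (< 3 pixels)")
  t <- w[, 1] * axis[1] + w[, 2] * axis[2]
  tstar <- if (end == "min") min(t) else max(t)
  sel <- abs(t - tstar) <= tie_px
  colMeans(w[sel, , drop = FALSE])
}

# arc-length position (in boundary pixel units) of points along the arch:
# each point maps to the arc of its nearest boundary point
arc_position <- function(pts, profile) {
  # project onto the scallop-free smooth curve: the raw contour bulges
  # around every crown, and nearest-point mapping against a scalloped curve
  # folds tooth-center pixels onto the flanking notches (a caustic)
  sm <- profile$smooth
  if (is.null(sm)) {
    b <- profile$boundary; arcs <- profile$arc; tgs <- profile$tangents
  } else {
    b <- sm$points; arcs <- sm$arc; tgs <- sm$tangents
  }
  out <- numeric(nrow(pts))
  chunk <- 2000L
  for (st in seq(1L, nrow(pts), by = chunk)) {
    en <- min(nrow(pts), st + chunk - 1L)
    d2 <- outer(pts[st:en, 1], b[, 1], "-")^2 +
      outer(pts[st:en, 2], b[, 2], "-")^2
    ni <- max.col(-d2, ties.method = "first")
    # continuous refinement along the local tangent
    tg <- tgs[ni, , drop = FALSE]
    res <- pts[st:en, , drop = FALSE] - b[ni, , drop = FALSE]
    out[st:en] <- arcs[ni] + rowSums(res * tg)
  }
  out
}

# linear binning with a light 1-2-1 smooth: hard rounding of projections
# onto an oblique axis produces moire oscillations that masquerade as
# valleys
bin_profile <- function(t_rel) {
  k_rng <- floor(min(t_rel)):ceiling(max(t_rel))
  nvec <- numeric(length(k_rng))
  klo <- floor(t_rel) - k_rng[1] + 1L
  fr <- t_rel - floor(t_rel)
  for (ii in seq_along(t_rel)) {
    nvec[klo[ii]] <- nvec[klo[ii]] + (1 - fr[ii])
    if (klo[ii] < length(nvec)) nvec[klo[ii] + 1L] <- nvec[klo[ii] + 1L] + fr[ii]
  }
  if (length(nvec) >= 3) {
    sm <- stats::filter(nvec, c(1, 2, 1) / 4, sides = 2)
    sm[is.na(sm)] <- nvec[is.na(sm)]
    nvec <- as.numeric(sm)
  }
  list(counts = nvec, kvals = k_rng)
}

# outward walk from the tooth center to the interproximal valley; returns
# the edge bin (in the same relative units as t_rel)
valley_walk <- function(bp, t_mask_rel, end, valley_frac = 0.5,
                        kmax_px = NULL) {
  counts <- bp$counts; kvals <- bp$kvals
  span <- max(1, round((max(t_mask_rel) - min(t_mask_rel)) / 4))
  base <- stats::median(counts[abs(kvals) <= span])
  if (!is.finite(base) || base <= 0) base <- max(counts)
  vthr <- valley_frac * base
  rise <- max(2, 0.12 * base)
  step <- if (end == "min") -1L else 1L
  # reach: the mask span plus slack, but never less than a plausible crown
  # half-width -- an undersized instance mask must not truncate the walk
  kmax <- if (end == "min") round(-min(t_mask_rel)) + 3L
          else round(max(t_mask_rel)) + 3L
  if (!is.null(kmax_px)) kmax <- max(kmax, as.integer(kmax_px))
  at <- function(k) { v <- counts[match(k, kvals)]; if (is.na(v)) 0 else v }
  k <- 0L; edge <- 0L; last_occ <- 0L
  min_val <- base; k_min <- 0L
  repeat {
    k <- k + step
    n_k <- at(k)
    if (n_k < 0.25) { edge <- last_occ; break }     # free end: last occupied
    last_occ <- k
    if (n_k <= vthr) {
      # deep contact valley: follow it down to the trough center
      while (at(k + step) > 0.25 && at(k + step) < n_k) {
        k <- k + step; n_k <- at(k)
      }
      edge <- k; break
    }
    if (n_k < min_val) { min_val <- n_k; k_min <- k }
    else if (min_val < 0.85 * base && n_k > min_val + rise) {
      edge <- k_min; break                           # shallow valley passed
    }
    if (abs(k) >= kmax) { edge <- k; break }        # no valley: mask extreme
  }
  edge
}

# Landmark at one end of a tooth, placed at the interproximal neck: the
# foreground footprint (all teeth in the window) is binned along the arch
# arc coordinate (or along the straight mesio-distal axis when no profile is
# available) and the walk from the tooth center stops at the first
# pixel-count valley -- the contact -- or at the last occupied bin of a free
# end. Instance-split boundaries (watershed) are deliberately not trusted
# here: flooding splits bite into the larger of two fused crowns, while the
# footprint neck sits at the true contact point. The arc coordinate keeps
# the contact planes of tilted neighbors phase-aligned where a straight
# projection smears them.
interproximal_extreme <- function(win, end = c("min", "max"),
                                  valley_frac = 0.5) {
  end <- match.arg(end)
  wm <- which(win$mask, arr.ind = TRUE)
  if (nrow(wm) < 3) stop("degenerate tooth mask (< 3 pixels)")
  wf <- which(win$fg | win$mask, arr.ind = TRUE)
  if (!is.null(win$profile)) {
    tm <- arc_position(sweep(wm, 2, win$offset, "+"), win$profile)
    tf <- arc_position(sweep(wf, 2, win$offset, "+"), win$profile)
  } else {
    tm <- wm[, 1] * win$axis[1] + wm[, 2] * win$axis[2]
    tf <- wf[, 1] * win$axis[1] + wf[, 2] * win$axis[2]
  }
  t0 <- stats::median(tm)
  edge <- valley_walk(bin_profile(tf - t0), tm - t0, end,
                      valley_frac = valley_frac, kmax_px = win$kmax_px)
  sel <- abs((tf - t0) - edge) <= 0.6
  if (!any(sel)) sel <- abs((tf - t0) - edge) <= 1.1
  colMeans(wf[sel, , drop = FALSE])
}

#' Reference landmark backend: interproximal extremes along the arch
#'
#' The classical per-tooth landmark detector: each landmark is the
#' projection-profile extreme of the tooth along the arch -- the first
#' pixel-count valley of the footprint on each side of the tooth center
#' (the interproximal contact), or the last occupied bin at a free end.
#' Which end is mesial is decided by the caller from the tooth's side
#' (mesial is the end nearer the midline along the arch).
#'
#' @param roi a `tooth_roi`.
#' @return object of class `landmark_pair`: `lo`, `hi` (crop coordinates of
#'   the decreasing-arc and increasing-arc ends), `offset`, `axis`,
#'   `backend`, `flag`.
#' @export
reference_landmark_backend <- function(roi) {
  stopifnot(inherits(roi, "tooth_roi"))
  if (sum(roi$mask) < 3) stop("degenerate tooth mask (< 3 pixels)")
  win <- roi_window(roi)
  lo <- interproximal_extreme(win, "min")
  hi <- interproximal_extreme(win, "max")
  structure(list(lo = lo, hi = hi, offset = roi$offset, axis = roi$axis,
                 backend = "reference", depth = 1L, flag = ""),
            class = "landmark_pair")
}

# stage window view of a full ROI (or of a sub-crop at extra offset)
roi_window <- function(roi, img = roi$img, mask = roi$mask, fg = roi$fg,
                       extra_offset = c(0L, 0L)) {
  list(img = img, mask = mask, fg = fg, axis = roi$axis,
       offset = roi$offset + extra_offset, profile = roi$profile,
       kmax_px = round(6.8 / mean(roi$spacing)))  # half the largest crown + slack
}

#' Mesio-distal width from a lifted landmark pair
#'
#' Plain 3D Euclidean distance in mm between the two landmarks.
#'
#' @param p1,p2 numeric length-3 mm coordinates (mesial and distal
#'   landmarks).
#' @return distance in mm.
#' @export
mesiodistal_width <- function(p1, p2) {
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Lift a 2D landmark to 3D through a depth map
#'
#' Takes z from the nearest valid depth cell within a 3-cell search radius
#' and converts all three coordinates to mm. For voxel-unit depth maps the
#' stored z is a zero-based axial index and is scaled by `spacing[3]`; a
#' mm-unit depth map reports z as stored and maps x, y through its own grid
#' geometry.
#'
#' @param point2d 1-based pixel/cell coordinates `(i, j)` on the depth grid.
#' @param depth a [depth_map].
#' @param spacing volume spacing (mm) for voxel-unit depth maps.
#' @param radius nearest-valid-cell search radius in cells.
#' @return numeric length-3 mm coordinate.
#' @export
lift_to_3d <- function(point2d, depth, spacing = c(1, 1, 1), radius = 3L) {
  stopifnot(inherits(depth, "depth_map"))
  z <- depth_at(depth, point2d[1], point2d[2], radius)
  if (is.na(z)) stop("landmark off tooth surface: no valid depth within ",
                     radius, " cells")
  if (depth$units == "voxel") {
    c((point2d[1] - 0.5) * spacing[1], (point2d[2] - 0.5) * spacing[2],
      z * spacing[3])
  } else {
    c(depth$origin[1] + (point2d[1] - 0.5) * depth$spacing[1],
      depth$origin[2] + (point2d[2] - 0.5) * depth$spacing[2],
      z)
  }
}

#' Cusp tips from a bucco-lingual depth profile
#'
#' Samples a 1D depth profile along the bucco-lingual direction
#' (perpendicular to the tooth's mesio-distal axis) through the
#' landmark-pair midpoint -- for the 1st molar through the point 1/4 of the
#' way from the mesial landmark, to target the mesio-buccal cusp -- and
#' locates cusp tips as profile peaks with topographic prominence above a
#' threshold. The buccal tip is the peak on the side away from the arch
#' centroid; a canine reports its single highest-prominence peak.
#'
#' @param pair_mm list with `mesial` and `distal` 3D mm landmarks.
#' @param depth a mm-unit [depth_map] (scan-derived).
#' @param md_axis_mm unit mesio-distal direction in the (x, y) mm plane.
#' @param centroid_mm arch centroid in mm (for the buccal side rule).
#' @param pos tooth position 1..6 (3 canine, 4/5 premolar, 6 molar).
#' @param prominence_mm minimum peak prominence in mm.
#' @param half_span_mm profile half-length in mm.
#' @return list with `buccal` (3D mm), `lingual` (3D mm or NULL), `profile`
#'   (tibble `t_mm`, `z_mm`).
#' @export
cusp_tips <- function(pair_mm, depth, md_axis_mm, centroid_mm, pos,
                      prominence_mm = 0.5, half_span_mm = 6) {
  stopifnot(inherits(depth, "depth_map"), depth$units == "mm")
  base <- if (pos == 6) {
    pair_mm$mesial[1:2] + 0.25 * (pair_mm$distal[1:2] - pair_mm$mesial[1:2])
  } else {
    (pair_mm$mesial[1:2] + pair_mm$distal[1:2]) / 2
  }
  v <- c(-md_axis_mm[2], md_axis_mm[1])
  if (sum(v * (base - centroid_mm)) < 0) v <- -v   # +t is buccal
  step <- mean(depth$spacing) / 2
  ts <- seq(-half_span_mm, half_span_mm, by = step)
  pts_x <- base[1] + ts * v[1]; pts_y <- base[2] + ts * v[2]
  gi <- (pts_x - depth$origin[1]) / depth$spacing[1] + 0.5
  gj <- (pts_y - depth$origin[2]) / depth$spacing[2] + 0.5
  zz <- vapply(seq_along(ts), function(k) {
    z <- depth_at(depth, gi[k], gj[k], radius = 1L)
    if (is.na(z)) -Inf else z
  }, numeric(1))
  fin <- is.finite(zz)
  if (!any(fin)) stop("cusp not found: profile off the tooth surface")
  zf <- zz[fin]; tf <- ts[fin]
  # light smoothing against rasterization plateaus
  if (length(zf) >= 5) {
    sm <- as.numeric(stats::filter(zf, rep(1 / 3, 3), sides = 2))
    sm[is.na(sm)] <- zf[is.na(sm)]
    zf <- sm
  }
  pk <- find_peaks(as.numeric(zf), min_prominence = prominence_mm)
  if (nrow(pk) == 0) stop("cusp not found: no peak above prominence ",
                          prominence_mm, " mm")
  tip3 <- function(row) c(base[1] + tf[row$index] * v[1],
                          base[2] + tf[row$index] * v[2], row$value)
  if (pos == 3) {
    best <- pk[which.max(pk$prominence), ]
    return(list(buccal = tip3(best), lingual = NULL,
                profile = tibble::tibble(t_mm = tf, z_mm = as.numeric(zf))))
  }
  bpk <- pk[tf[pk$index] > 0, ]; lpk <- pk[tf[pk$index] < 0, ]
  if (nrow(bpk) == 0) stop("cusp not found: no buccal peak")
  b <- bpk[which.max(bpk$value), ]
  l <- if (nrow(lpk)) lpk[which.max(lpk$value), ] else NULL
  list(buccal = tip3(b), lingual = if (!is.null(l)) tip3(l),
       profile = tibble::tibble(t_mm = tf, z_mm = as.numeric(zf)))
}

#' Arch widths from paired cusp tips
#'
#' Inter-canine, inter-premolar and inter-first-molar distances: the 3D
#' Euclidean distances between the left and right canine cusp tips, 1st
#' premolar buccal cusp tips, and 1st molar mesio-buccal cusp tips. A
#' parameter whose side is missing is reported absent.
#'
#' @param tips tibble with columns `side` ("L"/"R"), `pos` (3, 4 or 6) and
#'   `x`, `y`, `z` mm tip coordinates.
#' @return tibble with columns `parameter`, `width_mm`.
#' @export
arch_widths <- function(tips) {
  out <- list()
  for (pp in c(canine = 3, premolar = 4, molar = 6)) {
    L <- tips[tips$side == "L" & tips$pos == pp, ]
    R <- tips[tips$side == "R" & tips$pos == pp, ]
    if (nrow(L) == 1 && nrow(R) == 1) {
      out[[length(out) + 1L]] <- tibble::tibble(
        parameter = names(which(c(canine = 3, premolar = 4, molar = 6) == pp)),
        width_mm = sqrt((L$x - R$x)^2 + (L$y - R$y)^2 + (L$z - R$z)^2))
    }
  }
  dplyr::bind_rows(out)
}
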