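#' Synthetic dental phantom specification
#'
#' Describes a two-arch dental phantom: 12 teeth per jaw (right 1st molar to
#' left 1st molar, positions 1--6 per side in FDI-style numbering), placed
#' tangentially along a parabolic arch. Defaults reproduce average adult
#' clinical dimensions: per-tooth mesio-distal widths of 7.25, 6.74, 7.63,
#' 7.66, 7.36 and 11.03 mm (central incisor through 1st molar), 0.3 mm voxel
#' spacing, and an arch coefficient chosen so the true inter-canine,
#' inter-premolar and inter-first-molar cusp distances fall near 30.4, 38.5
#' and 50.6 mm.
#'
#' @param widths per-tooth mesio-distal widths in mm for positions 1..6
#'   (central incisor .. 1st molar). Either a length-6 vector applied to both
#'   jaws or `list(upper =, lower =)`.
#' @param bl_depths bucco-lingual crown depths (mm), positions 1..6.
#' @param crown_heights crown heights (mm), positions 1..6.
#' @param arch_coef parabola coefficient a of the arch `y = a x^2` (1/mm);
#'   larger values give a deeper, narrower arch.
#' @param gap_mm inter-jaw occlusal gap in mm; 0 is a closed bite (cusp
#'   contact), negative values overlap.
#' @param alpha_deg jaw inclination: rotation of the whole dentition about
#'   the frontal (x) axis, degrees.
#' @param theta_deg in-plane rotation about the axial (z) axis, degrees.
#' @param crowding optional data frame with columns `jaw` ("upper"/"lower"),
#'   `side` ("L"/"R"), `pos` (1..6), `du_mm` (shift along the local
#'   mesio-distal axis), `dv_mm` (buccal shift) and `rot_deg` (tooth rotation
#'   about z), modelling crowded/rotated teeth.
#' @param missing optional data frame with columns `jaw`, `side`, `pos` of
#'   teeth to omit.
#' @param noise_sd additive Gaussian intensity noise (HU-like units).
#' @param metal_streaks logical; add radial high-intensity streaks through a
#'   randomly chosen molar.
#' @param spacing voxel spacing in mm (scalar or length-3).
#' @param squareness superellipsoid exponents `c(md, bl, z)` controlling how
#'   box-like a crown is along each local axis; the high mesio-distal
#'   exponent keeps the rendered extent analytically close to the nominal
#'   width while the rounded bucco-lingual profile (exponent 2) models the
#'   curved crown flanks that open interproximal embrasures between
#'   contacting teeth.
#' @param color_jitter per-channel HSV jitter s.d. for scan phantoms.
#' @param point_spacing_mm sampling pitch of the scan-phantom point grid.
#' @param seed integer random seed; generation is deterministic given the
#'   spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(widths = NULL,
                         bl_depths = c(6.5, 6.0, 7.5, 9.0, 9.0, 10.5),
                         crown_heights = c(9.0, 8.5, 10.0, 8.0, 7.5, 7.0),
                         arch_coef = 0.056,
                         gap_mm = 4,
                         alpha_deg = 0,
                         theta_deg = 0,
                         crowding = NULL,
                         missing = NULL,
                         noise_sd = 50,
                         metal_streaks = FALSE,
                         spacing = 0.3,
                         squareness = c(md = 4, bl = 2, z = 2.4),
                         color_jitter = 0.02,
                         point_spacing_mm = 0.15,
                         seed = 1L) {
  table1 <- c(7.25, 6.74, 7.63, 7.66, 7.36, 11.03)
  if (is.null(widths)) widths <- table1
  if (!is.list(widths)) widths <- list(upper = widths, lower = widths)
  for (j in c("upper", "lower")) {
    if (length(widths[[j]]) != 6L || any(widths[[j]] <= 0))
      stop("widths must be 6 positive values per jaw")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!is.finite(alpha_deg) || abs(alpha_deg) > 60)
    stop("alpha_deg must be finite and within +/-60 degrees")
  structure(list(
    widths = widths, bl_depths = bl_depths, crown_heights = crown_heights,
    arch_coef = arch_coef, gap_mm = gap_mm, alpha_deg = alpha_deg,
    theta_deg = theta_deg, crowding = crowding, missing = missing,
    noise_sd = noise_sd, metal_streaks = metal_streaks, spacing = spacing,
    squareness = squareness, color_jitter = color_jitter,
    point_spacing_mm = point_spacing_mm, seed = as.integer(seed)),
    class = "phantom_spec")
}

# run code with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}

# arc length along y = a x^2 from 0 to x
arch_arclen <- function(x, a) {
  u <- 2 * a * x
  (u * sqrt(1 + u^2) + asinh(u)) / (4 * a)
}

arch_x_at_arc <- function(s, a) {
  vapply(s, function(si)
    stats::uniroot(function(x) arch_arclen(x, a) - si, c(0, 500))$root,
    numeric(1))
}

# Lay out the 12 teeth of one jaw along the arch. Returns a list of per-tooth
# frames in neutral (unrotated) coordinates: center2d, tangent u2d pointing
# distal, buccal normal v2d, plus dimensions.
layout_jaw <- function(spec, jaw) {
  w <- spec$widths[[jaw]]
  a <- spec$arch_coef
  arcs <- cumsum(w) - w / 2
  xs <- arch_x_at_arc(arcs, a)
  frames <- list()
  for (side in c("R", "L")) {
    sgn <- if (side == "R") 1 else -1
    for (k in 1:6) {
      xk <- sgn * xs[k]; yk <- a * xk^2
      tg <- c(1, 2 * a * xk); tg <- tg / sqrt(sum(tg^2))
      u2d <- sgn * tg                       # distal direction
      v2d <- c(2 * a * xk, -1); v2d <- v2d / sqrt(sum(v2d^2))
      if (sum(v2d * c(xk, yk - 16)) < 0) v2d <- -v2d   # buccal: outward
      fr <- list(jaw = jaw, side = side, pos = k,
                 center2d = c(xk, yk), u2d = u2d, v2d = v2d,
                 w = w[k], bl = spec$bl_depths[k], h = spec$crown_heights[k])
      if (!is.null(spec$crowding)) {
        cr <- spec$crowding
        hit <- cr$jaw == jaw & cr$side == side & cr$pos == k
        if (any(hit)) {
          cr <- cr[which(hit)[1], ]
          fr$center2d <- fr$center2d + cr$du_mm * fr$u2d + cr$dv_mm * fr$v2d
          R <- rot2(cr$rot_deg)
          fr$u2d <- as.vector(R %*% fr$u2d)
          fr$v2d <- as.vector(R %*% fr$v2d)
        }
      }
      if (!is.null(spec$missing)) {
        mi <- spec$missing
        if (any(mi$jaw == jaw & mi$side == side & mi$pos == k)) next
      }
      frames[[length(frames) + 1L]] <- fr
    }
  }
  frames
}

# cusp layout in the local (u distal, v buccal) tooth frame: offsets in mm
# and bump amplitudes; NULL for incisors (incisal edge, no cusp modelled)
cusp_layout <- function(fr) {
  bv <- fr$bl / 2
  switch(as.character(fr$pos),
    "3" = data.frame(u = 0, v = 0.5 * bv, amp = 1.3,
                     role = "buccal", stringsAsFactors = FALSE),
    "4" = , "5" = data.frame(u = c(0, 0), v = c(0.45, -0.45) * bv,
                             amp = c(1.1, 0.9), role = c("buccal", "lingual")),
    "6" = data.frame(u = c(-1, 1, -1, 1) * fr$w / 4,
                     v = c(0.45, 0.45, -0.45, -0.45) * bv,
                     amp = c(1.15, 0.95, 0.9, 0.8),
                     role = c("buccal", "distobuccal", "lingual",
                              "distolingual")),
    NULL)
}

# scene rotation (theta about z, then alpha about x is applied first:
# R = Rz(theta) %*% Rx(alpha)) around a pivot in world mm
scene_rotation <- function(spec, pivot) {
  R <- rot3_z(spec$theta_deg) %*% rot3_x(spec$alpha_deg)
  list(R = R, pivot = pivot)
}

rotate_pts <- function(rot, p) {
  sweep(sweep(p, 2, rot$pivot) %*% t(rot$R), 2, rot$pivot, "+")
}

tooth_ids <- function(frames, jaw) {
  base <- if (jaw == "upper") 0L else 12L
  vapply(frames, function(fr)
    base + (if (fr$side == "R") 0L else 6L) + fr$pos, integer(1))
}

#' Generate a CBCT-like voxel phantom of two dental arches
#'
#' Renders 24 crown superellipsoids (12 per jaw) tangentially along a
#' parabolic arch inside a volume that also contains a soft-tissue ellipse
#' (~300), per-jaw alveolar bone bands (~900) and additive Gaussian noise;
#' crowns are ~1600 and optional metal streaks ~3000 (HU-like arbitrary
#' units). The accompanying ground truth records every true landmark, width,
#' cusp tip, midline, and a voxel-level tooth/jaw label volume.
#'
#' @param spec a [phantom_spec].
#' @return a list with elements `volume` (a [voxel_volume]) and `truth`
#'   (a `phantom_truth`: see Details).
#' @details The `truth` object contains `teeth` (a tibble with tooth id, jaw,
#'   side, position, true mesial/distal landmarks and width, and cusp tips
#'   for canine/premolars/molar), `label` (integer array of per-voxel tooth
#'   ids, 0 = background), `jaw_label` (1 upper / 2 lower / 0), `midline`
#'   (true midline point and in-plane axis per jaw), `arch_widths`,
#'   the applied rotation angles, and an `overlap_voxels` count of
#'   crowding-induced tooth overlaps (a warning-level quantity, not an
#'   error).
#' @export
generate_cbct_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  # The volume emulates a teeth-region crop bounded anteriorly by the
  # incisors and posteriorly by the jaw joint (condyle) region, so the
  # dentition sits in the anterior part of the frame as it does in a
  # cephalometrically cropped CBCT; the posterior part holds only soft
  # tissue.
  origin <- c(-33, -9, -22)
  extent <- c(66, 84, 44)
  dims <- as.integer(round(extent / sp))
  pivot <- origin + extent / 2
  rot <- scene_rotation(spec, pivot)

  vol <- array(0, dims)
  lab <- array(0L, dims)
  xs_mm <- origin[1] + (seq_len(dims[1]) - 0.5) * sp[1]
  ys_mm <- origin[2] + (seq_len(dims[2]) - 0.5) * sp[2]
  zs_mm <- origin[3] + (seq_len(dims[3]) - 0.5) * sp[3]
  identity_rot <- spec$alpha_deg == 0 && spec$theta_deg == 0

  # soft tissue + bone bands, slice by slice (the inverse rotation mixes z)
  a <- spec$arch_coef
  xg <- rep(xs_mm, times = dims[2])
  yg <- rep(ys_mm, each = dims[1])
  maxh <- max(spec$crown_heights)
  bone_z <- list(upper = spec$gap_mm / 2 + maxh + c(0.5, 6.5),
                 lower = -spec$gap_mm / 2 - maxh - c(6.5, 0.5))
  soft2d <- NULL
  for (k in seq_len(dims[3])) {
    if (identity_rot && !is.null(soft2d)) {
      p0x <- xg; p0y <- yg; p0z <- zs_mm[k]
      soft <- soft2d
    } else {
      p <- cbind(xg, yg, zs_mm[k])
      p0 <- sweep(sweep(p, 2, rot$pivot) %*% rot$R, 2, rot$pivot, "+")
      p0x <- p0[, 1]; p0y <- p0[, 2]; p0z <- p0[, 3]
      soft <- (p0x / 31)^2 + ((p0y - 30) / 42)^2 <= 1
      if (identity_rot) soft2d <- soft
    }
    slice <- vol[, , k]
    slice[soft] <- 300
    dperp <- abs(p0y - a * p0x^2) / sqrt(1 + (2 * a * p0x)^2)
    ridge_end <- max(sapply(spec$widths, sum)) + 4  # band ends past the molars
    band <- dperp <= 3.5 & arch_arclen(abs(p0x), a) <= ridge_end
    for (j in c("upper", "lower")) {
      bz <- bone_z[[j]]
      inb <- if (identity_rot) (zs_mm[k] >= bz[1] & zs_mm[k] <= bz[2])
             else NULL
      sel <- if (identity_rot) { if (inb) band else FALSE }
             else band & p0z >= bz[1] & p0z <= bz[2]
      slice[sel] <- 900
    }
    vol[, , k] <- slice
  }

  frames <- c(layout_jaw(spec, "upper"), layout_jaw(spec, "lower"))
  jaws <- vapply(frames, `[[`, character(1), "jaw")
  ids <- integer(length(frames))
  ids[jaws == "upper"] <- tooth_ids(frames[jaws == "upper"], "upper")
  ids[jaws == "lower"] <- tooth_ids(frames[jaws == "lower"], "lower")
  pz <- spec$squareness[["z"]]; pmd <- spec$squareness[["md"]]
  pbl <- spec$squareness[["bl"]]
  overlap <- 0L
  teeth_rows <- list()
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    up <- fr$jaw == "upper"
    zc <- if (up) spec$gap_mm / 2 + fr$h / 2 else -spec$gap_mm / 2 - fr$h / 2
    c3 <- c(fr$center2d, zc)
    U <- c(fr$u2d, 0); V <- c(fr$v2d, 0); W <- c(0, 0, 1)
    c3r <- as.vector(rotate_pts(rot, rbind(c3)))
    Ur <- as.vector(rot$R %*% U); Vr <- as.vector(rot$R %*% V)
    Wr <- as.vector(rot$R %*% W)
    aw <- fr$w / 2; bv <- fr$bl / 2; cz <- fr$h / 2
    e <- sqrt(aw^2 + bv^2 + cz^2) + max(sp)
    i_rng <- which(abs(xs_mm - c3r[1]) <= e)
    j_rng <- which(abs(ys_mm - c3r[2]) <= e)
    k_rng <- which(abs(zs_mm - c3r[3]) <= e)
    if (!length(i_rng) || !length(j_rng) || !length(k_rng)) next
    gx <- xs_mm[i_rng] - c3r[1]; gy <- ys_mm[j_rng] - c3r[2]
    gz <- zs_mm[k_rng] - c3r[3]
    px <- rep(gx, times = length(gy) * length(gz))
    py <- rep(rep(gy, each = length(gx)), times = length(gz))
    pzv <- rep(gz, each = length(gx) * length(gy))
    q1 <- px * Ur[1] + py * Ur[2] + pzv * Ur[3]
    q2 <- px * Vr[1] + py * Vr[2] + pzv * Vr[3]
    q3 <- px * Wr[1] + py * Wr[2] + pzv * Wr[3]
    inside <- (abs(q1 / aw)^pmd + abs(q2 / bv)^pbl + abs(q3 / cz)^pz) <= 1
    if (any(inside)) {
      idx <- cbind(
        rep(i_rng, times = length(j_rng) * length(k_rng))[inside],
        rep(rep(j_rng, each = length(i_rng)), times = length(k_rng))[inside],
        rep(k_rng, each = length(i_rng) * length(j_rng))[inside])
      prev <- lab[idx]
      overlap <- overlap + sum(prev != 0L & prev != ids[t])
      vol[idx] <- 1600
      lab[idx] <- ids[t]
    }
    # truth: landmarks at crown mid-height, occlusal-plane cusp tips
    mes <- rotate_pts(rot, rbind(c3 - aw * U))
    dis <- rotate_pts(rot, rbind(c3 + aw * U))
    occ_z <- if (up) spec$gap_mm / 2 else -spec$gap_mm / 2
    cl <- cusp_layout(fr)
    tipb <- tipl <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(cl)) {
      tips <- lapply(seq_len(nrow(cl)), function(r) {
        p2 <- fr$center2d + cl$u[r] * fr$u2d + cl$v[r] * fr$v2d
        as.vector(rotate_pts(rot, rbind(c(p2, occ_z))))
      })
      tipb <- tips[[which(cl$role == "buccal")[1]]]
      if (any(cl$role == "lingual")) tipl <- tips[[which(cl$role == "lingual")[1]]]
    }
    teeth_rows[[t]] <- tibble::tibble(
      tooth = ids[t], jaw = fr$jaw, side = fr$side, pos = fr$pos,
      cx = c3r[1], cy = c3r[2], cz = c3r[3],
      mes_x = mes[1], mes_y = mes[2], mes_z = mes[3],
      dis_x = dis[1], dis_y = dis[2], dis_z = dis[3],
      width_mm = sqrt(sum((dis - mes)^2)),
      tipb_x = tipb[1], tipb_y = tipb[2], tipb_z = tipb[3],
      tipl_x = tipl[1], tipl_y = tipl[2], tipl_z = tipl[3])
  }
  teeth <- dplyr::bind_rows(teeth_rows)

  if (isTRUE(spec$metal_streaks)) {
    with_seed(spec$seed + 7L, {
      molars <- teeth[teeth$pos == 6, ]
      m <- molars[sample.int(nrow(molars), 1L), ]
      angs <- stats::runif(8, 0, pi)
      k_rng <- which(abs(zs_mm - m$cz) <= 2)
      tt <- seq(-45, 45, by = min(sp) / 2)
      for (ang in angs) {
        lx <- m$cx + tt * cos(ang); ly <- m$cy + tt * sin(ang)
        ii <- round((lx - origin[1]) / sp[1] + 0.5)
        jj <- round((ly - origin[2]) / sp[2] + 0.5)
        ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2]
        for (k in k_rng) vol[cbind(ii[ok], jj[ok], k)] <- 3000
      }
    })
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
    })
  }

  jaw_label <- array(0L, dims)
  jaw_label[lab > 0L & lab <= 12L] <- 1L
  jaw_label[lab > 12L] <- 2L

  midline <- phantom_midline(spec, rot)
  truth <- structure(list(
    teeth = teeth, label = lab, jaw_label = jaw_label,
    midline = midline, arch_widths = truth_arch_widths(teeth),
    alpha_deg = spec$alpha_deg, theta_deg = spec$theta_deg,
    spacing = sp, origin = origin, pivot = pivot,
    overlap_voxels = overlap,
    kind = "cbct"), class = "phantom_truth")
  list(volume = voxel_volume(vol, spacing = sp, origin = origin),
       truth = truth)
}

phantom_midline <- function(spec, rot) {
  out <- list()
  for (j in c("upper", "lower")) {
    w1 <- spec$widths[[j]][1]
    y_front <- spec$arch_coef * (w1 / 2)^2 - spec$bl_depths[1] / 2
    occ_z <- if (j == "upper") spec$gap_mm / 2 else -spec$gap_mm / 2
    p <- as.vector(rotate_pts(rot, rbind(c(0, y_front, occ_z))))
    ax <- as.vector(rot$R %*% c(0, 1, 0))
    out[[j]] <- list(point = p, axis = ax[1:2] / sqrt(sum(ax[1:2]^2)))
  }
  out
}

truth_arch_widths <- function(teeth) {
  rows <- list()
  for (j in unique(teeth$jaw)) {
    tj <- teeth[teeth$jaw == j, ]
    for (pp in c(canine = 3, premolar = 4, molar = 6)) {
      L <- tj[tj$side == "L" & tj$pos == pp, ]
      R <- tj[tj$side == "R" & tj$pos == pp, ]
      if (nrow(L) == 1 && nrow(R) == 1 && is.finite(L$tipb_x)) {
        d <- sqrt((L$tipb_x - R$tipb_x)^2 + (L$tipb_y - R$tipb_y)^2 +
                    (L$tipb_z - R$tipb_z)^2)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          jaw = j, parameter = names(which(c(canine = 3, premolar = 4,
                                             molar = 6) == pp)),
          truth_mm = d)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s phantom, %d teeth, alpha=%g deg, theta=%g deg\n",
              x$kind, nrow(x$teeth), x$alpha_deg, x$theta_deg))
  if (x$overlap_voxels > 0)
    cat(sprintf("  note: %d overlapping crown voxels (crowding)\n",
                x$overlap_voxels))
  invisible(x)
}

#' Generate a colored scan phantom of one dental arch
#'
#' Emulates the colored surface scan of a plaster model: the occlusal surface
#' of one jaw is sampled as a point cloud, tooth points colored near-white
#' (low saturation, high value), gum points pink (hue around 0.97), each with
#' seeded HSV jitter. Crowns carry smooth Gaussian cusp bumps so
#' bucco-lingual depth profiles have distinct buccal and lingual peaks.
#' Ground-truth landmarks and cusp tips are computed by brute force over the
#' sampled labeled points (the mesial/distal landmarks are the extreme points
#' along each tooth's local mesio-distal axis; each cusp-tip truth is the
#' arg-max of z over the relevant quadrant of the tooth's points), so the
#' truth width equals the distance between its two landmark points exactly.
#'
#' @param spec a [phantom_spec]; `theta_deg` rotates the model in-plane
#'   (`alpha_deg` does not apply: plaster models are scanned occlusal-up).
#' @param jaw which arch to scan, "upper" or "lower".
#' @return list with `cloud` (a [colored_cloud] with a `label` column:
#'   tooth id, 0 = gum) and `truth` (a `phantom_truth`).
#' @export
generate_scan_phantom <- function(spec, jaw = c("upper", "lower")) {
  stopifnot(inherits(spec, "phantom_spec"))
  jaw <- match.arg(jaw)
  rot2d <- rot2(spec$theta_deg)
  frames <- layout_jaw(spec, jaw)
  ids <- tooth_ids(frames, jaw)
  ps <- spec$point_spacing_mm
  pmd <- spec$squareness[["md"]]; pbl <- spec$squareness[["bl"]]
  pz <- spec$squareness[["z"]]
  pts <- list(); labs <- list(); locs <- list()
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    aw <- fr$w / 2; bv <- fr$bl / 2
    u <- seq(-aw, aw, by = ps); v <- seq(-bv, bv, by = ps)
    g <- expand.grid(u = u, v = v)
    r <- abs(g$u / aw)^pmd + abs(g$v / bv)^pbl
    g <- g[r <= 1, ]; r <- r[r <= 1]
    zt <- 0.55 * fr$h * (1 - r)^(1 / pz)
    cl <- cusp_layout(fr)
    if (!is.null(cl)) {
      for (rr in seq_len(nrow(cl)))
        zt <- zt + cl$amp[rr] *
          exp(-((g$u - cl$u[rr])^2 + (g$v - cl$v[rr])^2) / (2 * 1.1^2))
    }
    p2 <- cbind(fr$center2d[1] + g$u * fr$u2d[1] + g$v * fr$v2d[1],
                fr$center2d[2] + g$u * fr$u2d[2] + g$v * fr$v2d[2])
    pts[[t]] <- cbind(p2, zt)
    labs[[t]] <- rep(ids[t], nrow(p2))
    locs[[t]] <- cbind(g$u, g$v)
  }
  # gum band following the arch, excluding tooth footprints
  a <- spec$arch_coef
  xr <- seq(-30, 30, by = ps * 1.6)
  yr <- seq(-6, 42, by = ps * 1.6)
  gg <- expand.grid(x = xr, y = yr)
  dperp <- abs(gg$y - a * gg$x^2) / sqrt(1 + (2 * a * gg$x)^2)
  gum_keep <- dperp <= max(spec$bl_depths) / 2 + 2.5 &
    arch_arclen(abs(gg$x), a) <= sum(spec$widths[[jaw]]) + 4
  gg <- gg[gum_keep, ]
  in_tooth <- rep(FALSE, nrow(gg))
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    du <- (gg$x - fr$center2d[1]) * fr$u2d[1] +
      (gg$y - fr$center2d[2]) * fr$u2d[2]
    dv <- (gg$x - fr$center2d[1]) * fr$v2d[1] +
      (gg$y - fr$center2d[2]) * fr$v2d[2]
    in_tooth <- in_tooth |
      (abs(du / (fr$w / 2 + 0.25))^pmd + abs(dv / (fr$bl / 2 + 0.25))^pbl) <= 1
  }
  gg <- gg[!in_tooth, ]
  gum_z <- -0.8 - 0.05 * (gg$y - a * gg$x^2)
  n_tooth <- sum(vapply(pts, nrow, integer(1)))
  n_gum <- nrow(gg)
  xyz <- rbind(do.call(rbind, pts), cbind(as.matrix(gg), gum_z))
  label <- c(unlist(labs), rep(0L, n_gum))
  # in-plane rotation about the arch pivot (0, 18)
  pivot2 <- c(0, 18)
  xyz[, 1:2] <- sweep(sweep(xyz[, 1:2], 2, pivot2) %*% t(rot2d), 2, pivot2, "+")
  col <- with_seed(spec$seed + 1L, phantom_colors(label, spec$color_jitter))
  cloud <- colored_cloud(xyz, col, label = label)

  # truth by brute force over labeled sample points
  u_all <- do.call(rbind, locs)
  teeth_rows <- list()
  off <- 0L
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    n <- nrow(pts[[t]])
    seg <- (off + 1L):(off + n); off <- off + n
    P <- xyz[seg, , drop = FALSE]
    dimnames(P) <- NULL
    uu <- u_all[seg, 1]; vv <- u_all[seg, 2]
    i_mes <- which.min(uu); i_dis <- which.max(uu)
    mes <- P[i_mes, ]; dis <- P[i_dis, ]
    cl <- cusp_layout(fr)
    tipb <- tipl <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(cl)) {
      if (fr$pos == 3) {
        tipb <- P[which.max(P[, 3]), ]
      } else if (fr$pos %in% c(4, 5)) {
        bsel <- vv > 0; lsel <- vv < 0
        tipb <- P[bsel, , drop = FALSE][which.max(P[bsel, 3]), ]
        tipl <- P[lsel, , drop = FALSE][which.max(P[lsel, 3]), ]
      } else {
        bsel <- vv > 0 & uu < 0; lsel <- vv < 0 & uu < 0
        tipb <- P[bsel, , drop = FALSE][which.max(P[bsel, 3]), ]
        tipl <- P[lsel, , drop = FALSE][which.max(P[lsel, 3]), ]
      }
    }
    c2r <- as.vector(sweep(rbind(fr$center2d), 2, pivot2) %*% t(rot2d) + pivot2)
    teeth_rows[[t]] <- tibble::tibble(
      tooth = ids[t], jaw = fr$jaw, side = fr$side, pos = fr$pos,
      cx = c2r[1], cy = c2r[2], cz = 0.55 * fr$h,
      mes_x = mes[1], mes_y = mes[2], mes_z = mes[3],
      dis_x = dis[1], dis_y = dis[2], dis_z = dis[3],
      width_mm = sqrt(sum((dis - mes)^2)),
      tipb_x = tipb[1], tipb_y = tipb[2], tipb_z = tipb[3],
      tipl_x = tipl[1], tipl_y = tipl[2], tipl_z = tipl[3])
  }
  teeth <- dplyr::bind_rows(teeth_rows)
  y_front <- spec$arch_coef * (spec$widths[[jaw]][1] / 2)^2 -
    spec$bl_depths[1] / 2
  mid_p <- as.vector(sweep(rbind(c(0, y_front)), 2, pivot2) %*% t(rot2d) +
                       pivot2)
  mid_ax <- as.vector(rot2d %*% c(0, 1))
  midline <- list()
  midline[[jaw]] <- list(point = c(mid_p, 0), axis = mid_ax)
  truth <- structure(list(
    teeth = teeth, label = NULL, jaw_label = NULL, midline = midline,
    arch_widths = truth_arch_widths(teeth),
    alpha_deg = 0, theta_deg = spec$theta_deg, spacing = spec$spacing,
    origin = NULL, overlap_voxels = 0L, kind = "scan"),
    class = "phantom_truth")
  list(cloud = cloud, truth = truth)
}

# Seeded HSV color model shared by the scan phantom and the default FRNN
# training set: near-white teeth, pink gum.
phantom_colors <- function(label, jitter) {
  n <- length(label)
  tooth <- label > 0
  h <- s <- v <- numeric(n)
  nt <- sum(tooth); ng <- n - nt
  h[tooth] <- (0.11 + jitter * stats::rnorm(nt)) %% 1
  s[tooth] <- clamp(0.06 + jitter * stats::rnorm(nt), 0, 0.19)
  v[tooth] <- clamp(0.93 + jitter * stats::rnorm(nt), 0.5, 1)
  h[!tooth] <- (0.97 + jitter * stats::rnorm(ng)) %% 1
  s[!tooth] <- clamp(0.55 + 1.5 * jitter * stats::rnorm(ng), 0.41, 1)
  v[!tooth] <- clamp(0.78 + jitter * stats::rnorm(ng), 0.3, 1)
  cbind(h = h, s = s, v = v)
}

#' Labeled HSV training samples from the phantom color model
#'
#' Draws balanced teeth/gum color samples from the same seeded color model
#' the scan phantom uses, for training the fixed-radius nearest-neighbor
#' classifier. For real scans a user-supplied labeled sample table replaces
#' this.
#'
#' @param n_per_class samples per class.
#' @param jitter HSV jitter s.d.
#' @param seed RNG seed.
#' @return tibble with columns `h`, `s`, `v`, `label` (1 teeth, 2 gum).
#' @export
phantom_color_samples <- function(n_per_class = 200, jitter = 0.02,
                                  seed = 1L) {
  lab <- c(rep(1L, n_per_class), rep(0L, n_per_class))
  col <- with_seed(seed, phantom_colors(lab, jitter))
  tibble::tibble(h = col[, 1], s = col[, 2], v = col[, 3],
                 label = ifelse(lab > 0, 1L, 2L))
}
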