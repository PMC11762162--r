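#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end runs. Every numeric
#' field is range-checked; unknown fields are rejected.
#'
#' @param roi optional [region_of_interest] to crop a CBCT volume to the
#'   teeth region before analysis (the crop bounds are pipeline inputs).
#' @param alpha jaw inclination in degrees, `"estimate"` for the fallback
#'   estimator, or a number (0 disables alignment).
#' @param w panoramic normal half-width in voxels.
#' @param frnn_radius FRNN candidate radius (HSV units).
#' @param frnn_samples labeled HSV training samples (tibble with h, s, v,
#'   label) or `NULL` for the phantom color model.
#' @param delta_d_mm midline near-tie slack in mm.
#' @param midline `"adaptive"` or `"fixed"`.
#' @param cascade a [cascade_detector()] or `NULL` for the single-stage
#'   reference backend.
#' @param min_spacing_mm minimum tooth peak separation for the detector.
#' @param prominence_mm cusp-peak prominence threshold in mm.
#' @param depth_cell_mm scan depth-map resolution in mm.
#' @param width_range_mm plausibility range; widths outside it are flagged.
#' @param metal_factor voxels brighter than this multiple of the enamel
#'   threshold are treated as metal-artifact streaks and suppressed.
#' @param seed RNG seed for any stochastic component.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(roi = NULL, alpha = 0, w = 15,
                            frnn_radius = 0.15, frnn_samples = NULL,
                            delta_d_mm = 0.6, midline = "adaptive",
                            cascade = NULL, min_spacing_mm = 3.5,
                            prominence_mm = 0.5, depth_cell_mm = 0.25,
                            width_range_mm = c(4, 14), metal_factor = 1.8,
                            seed = 1L) {
  stopifnot(w >= 1, frnn_radius > 0, delta_d_mm >= 0, min_spacing_mm > 0,
            prominence_mm > 0, depth_cell_mm > 0,
            length(width_range_mm) == 2, width_range_mm[1] < width_range_mm[2])
  if (!midline %in% c("adaptive", "fixed")) stop("unknown midline mode")
  structure(list(roi = roi, alpha = alpha, w = w, frnn_radius = frnn_radius,
                 frnn_samples = frnn_samples, delta_d_mm = delta_d_mm,
                 midline = midline, cascade = cascade,
                 min_spacing_mm = min_spacing_mm,
                 prominence_mm = prominence_mm,
                 depth_cell_mm = depth_cell_mm,
                 width_range_mm = width_range_mm,
                 metal_factor = metal_factor, seed = as.integer(seed)),
            class = "pipeline_config")
}

# occlusal-surface depth map of a binary jaw mask (after optional z flip)
depth_from_mask <- function(mask, flip_z = FALSE, spacing = c(1, 1, 1)) {
  if (flip_z) mask <- mask[, , rev(seq_len(dim(mask)[3])), drop = FALSE]
  d <- dim(mask)
  m <- matrix(mask, nrow = d[1] * d[2])
  first_k <- max.col(m, ties.method = "first")
  any_k <- m[cbind(seq_along(first_k), first_k)]
  z <- matrix(first_k - 1, d[1], d[2])
  valid <- matrix(any_k, d[1], d[2])
  z[!valid] <- NA_real_
  depth_map(z, valid, spacing = spacing[1:2], origin = c(0, 0),
            units = "voxel")
}

# measure one numbered detection on an image+depth pair; returns a tibble row
measure_tooth <- function(image, detections, id, profile, depth, config,
                          spacing3) {
  det <- detections$detections
  row <- det[det$id == id, ]
  flags <- row$flag
  res <- tibble::tibble(
    id = id, side = row$side, pos = row$pos,
    width_mm = NA_real_,
    mes_x = NA_real_, mes_y = NA_real_, mes_z = NA_real_,
    dis_x = NA_real_, dis_y = NA_real_, dis_z = NA_real_,
    flag = flags)
  out <- tryCatch({
    roi <- crop_tooth_roi(image, detections, id, profile,
                          spacing = spacing3[1:2])
    pair <- if (is.null(config$cascade)) reference_landmark_backend(roi)
            else run_cascade(config$cascade, roi)
    glo <- lapply(pair[c("lo", "hi")], function(p) p + roi$offset)
    # mesial end: nearer the midline along the arch. The roi axis points
    # toward increasing boundary arc (left distal -> midline -> right
    # distal), so on the right side increasing arc runs distally and the
    # min-projection end is mesial; on the left side it is the reverse.
    mes_is_lo <- identical(row$side, "R")
    ends <- if (mes_is_lo) list(mes = glo$lo, dis = glo$hi)
            else list(mes = glo$hi, dis = glo$lo)
    mes3 <- lift_to_3d(ends$mes, depth, spacing3)
    dis3 <- lift_to_3d(ends$dis, depth, spacing3)
    wmm <- mesiodistal_width(mes3, dis3)
    fl <- pair$flag
    if (wmm < config$width_range_mm[1] || wmm > config$width_range_mm[2])
      fl <- paste0(fl, ifelse(nzchar(fl), ";", ""), "implausible_width")
    res$width_mm <- wmm
    res[, c("mes_x", "mes_y", "mes_z")] <- as.list(mes3)
    res[, c("dis_x", "dis_y", "dis_z")] <- as.list(dis3)
    res$flag <- paste0(flags, ifelse(nzchar(flags) & nzchar(fl), ";", ""), fl)
    res
  }, error = function(e) {
    res$flag <- paste0(flags, ifelse(nzchar(flags), ";", ""),
                       "measurement_failed: ", conditionMessage(e))
    res
  })
  out
}

# arc direction check: does increasing boundary arc run distally on side R?
# The boundary runs left distal -> midline -> right distal, so yes; on side
# L increasing arc runs mesially, hence the min-axis end is distal there.
# (kept as documentation of the convention used in measure_tooth)

#' 3D upper/lower jaw separation
#'
#' Crops (when a ROI is configured), fits the arch curve on the mean axial
#' projection, extracts the panoramic image, splits panoramic tooth masks
#' into upper and lower sets, and assigns every sagittal-view slice mask to
#' a jaw through the panoramic projection of its representative point.
#'
#' @param volume a [voxel_volume].
#' @param config a [pipeline_config()].
#' @return list with `volume` (possibly cropped), `threshold` (the global
#'   enamel-level threshold), `curve`, `pano`, `pano_masks`, `assignment`
#'   (a `jaw_assignment`).
#' @export
separate_jaws <- function(volume, config = pipeline_config()) {
  stopifnot(inherits(volume, "voxel_volume"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(config$roi)) volume <- stage("crop", crop_volume(volume, config$roi))
  thr_teeth <- bright_tail_otsu(volume$data)
  # metal-artifact suppression: streak values far exceed enamel; voxels
  # above metal_factor x the enamel threshold are zeroed so radial streak
  # lines cannot merge with or displace tooth masks
  metal <- volume$data > config$metal_factor * thr_teeth
  if (any(metal)) {
    volume$data[metal] <- 0
    thr_teeth <- bright_tail_otsu(volume$data)
  }
  proj <- stage("arch", mean_axial_projection(volume))
  curve <- stage("arch", fit_arch_curve(proj))
  pano <- stage("panoramic", extract_panoramic(volume, curve, w = config$w))
  seg_slice <- slice_segmenter(
    threshold = thr_teeth,
    max_height_px = round(12 / volume$spacing[3]),   # > single-crown height
    max_width_px = round(13 / volume$spacing[1]))    # > widest single crown
  pano_masks <- stage("jaw_split", split_panoramic_masks(pano))
  jaws <- stage("jaw_assign",
                assign_jaws(volume, pano_masks, curve, w = config$w,
                            segmenter = seg_slice))
  list(volume = volume, threshold = thr_teeth, curve = curve, pano = pano,
       pano_masks = pano_masks, assignment = jaws)
}

#' Run the full CBCT measurement pipeline
#'
#' Crop, arch-curve fit, panoramic extraction, sagittal/panoramic jaw
#' separation, per-jaw MIP, tooth identification with the adaptive midline,
#' landmark detection and 3D lifting, and mesio-distal width measurement.
#' Per-tooth failures degrade to flags; stage-level failures propagate with
#' the stage name.
#'
#' @param volume a [voxel_volume] (CBCT-like, teeth region).
#' @param config a [pipeline_config()].
#' @return list of class `measurement_report`: `teeth` (tibble with jaw,
#'   side, pos, landmarks in mm, width, flags), `separation` (counts),
#'   `provenance`.
#' @export
run_cbct <- function(volume, config = pipeline_config()) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.numeric(config$alpha) && length(config$alpha) == 1 &&
      config$alpha != 0) {
    # a known inclination is leveled out before separation: the panoramic
    # jaw boundary is a straight line, which only separates level jaws
    volume <- stage("align", align_jaw(volume, config$alpha))
    config$alpha <- 0
  }
  sep <- separate_jaws(volume, config)
  volume <- sep$volume
  thr_teeth <- sep$threshold
  jaws <- sep$assignment
  rows <- list()
  for (jw in c("upper", "lower")) {
    mask <- if (jw == "upper") jaws$upper else jaws$lower
    mvol <- voxel_volume(volume$data * mask, spacing = volume$spacing,
                         origin = volume$origin)
    if (!identical(config$alpha, 0)) {
      al <- if (identical(config$alpha, "estimate")) NULL else config$alpha
      mvol <- stage("align", align_jaw(mvol, al, threshold = thr_teeth,
                                       jaw = jw))
      # the aligned teeth mask falls out of the aligned intensities
      mask <- mvol$data > thr_teeth
    }
    mip <- stage("mip", compute_mip(mvol, jaw = jw))
    det <- stage("detect", detect_teeth_on_mip(
      mip, threshold = thr_teeth, min_spacing_mm = config$min_spacing_mm))
    prof <- stage("profile", extract_jaw_profile(mip, threshold = thr_teeth))
    prof <- stage("midline", estimate_midline(
      prof, delta_d = config$delta_d_mm / mean(volume$spacing[1:2]),
      mode = config$midline))
    det <- stage("numbering", assign_fdi(det, prof))
    depth <- depth_from_mask(mask, flip_z = mip$flipped_z,
                             spacing = volume$spacing)
    for (id in det$detections$id) {
      r <- measure_tooth(mip$data, det, id, prof, depth, config,
                         volume$spacing)
      r$jaw <- jw
      # landmark mm coordinates are grid-local; shift to world mm
      for (cc in c("mes_x", "dis_x")) r[[cc]] <- r[[cc]] + volume$origin[1]
      for (cc in c("mes_y", "dis_y")) r[[cc]] <- r[[cc]] + volume$origin[2]
      rows[[length(rows) + 1L]] <- r
    }
  }
  teeth <- dplyr::bind_rows(rows)
  structure(list(
    teeth = teeth,
    separation = list(n_masks = jaws$n_masks,
                      n_unassigned = jaws$n_unassigned),
    provenance = list(kind = "cbct", w = config$w, midline = config$midline,
                      threshold = thr_teeth,
                      runtime_s = as.numeric(difftime(Sys.time(), t0, "secs")))),
    class = "measurement_report")
}

#' Run the full scan measurement pipeline
#'
#' FRNN teeth/gum segmentation of the colored cloud, depth-map conversion,
#' tooth identification on the depth map, landmark detection and lifting,
#' mesio-distal widths, cusp tips and arch widths.
#'
#' @param cloud a [colored_cloud] of one arch.
#' @param config a [pipeline_config()].
#' @return a `measurement_report` with `teeth`, `arch_widths`, `cusp_tips`,
#'   `provenance`.
#' @export
run_scan <- function(cloud, config = pipeline_config()) {
  stopifnot(inherits(cloud, "colored_cloud"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  samples <- config$frnn_samples %||% phantom_color_samples(seed = config$seed)
  model <- frnn_model(samples, R = config$frnn_radius)
  seg <- stage("frnn", teeth_cloud_and_depthmap(cloud, model,
                                                cell_mm = config$depth_cell_mm))
  det <- stage("identify", identify_from_depthmap(
    seg$depth, min_spacing_mm = config$min_spacing_mm,
    delta_d_mm = config$delta_d_mm, midline_mode = config$midline))
  prof <- det$profile
  depth <- seg$depth
  img <- depth$z
  img[!depth$valid] <- min(img, na.rm = TRUE) - 1
  rows <- list(); tips <- list()
  cen_mm <- c(depth$origin[1] + (prof$centroid[1] - 0.5) * depth$spacing[1],
              depth$origin[2] + (prof$centroid[2] - 0.5) * depth$spacing[2])
  for (id in det$detections$id) {
    r <- measure_tooth(img, det, id, prof, depth, config,
                       c(depth$spacing, 1))
    r$jaw <- NA_character_
    rows[[length(rows) + 1L]] <- r
    pp <- det$detections$pos[det$detections$id == id]
    sd <- det$detections$side[det$detections$id == id]
    if (!is.na(r$width_mm) && !is.na(pp) && pp %in% c(3, 4, 6)) {
      tip <- tryCatch({
        pair_mm <- list(mesial = c(r$mes_x, r$mes_y, r$mes_z),
                        distal = c(r$dis_x, r$dis_y, r$dis_z))
        md <- (pair_mm$distal[1:2] - pair_mm$mesial[1:2])
        md <- md / sqrt(sum(md^2))
        cusp_tips(pair_mm, depth, md, cen_mm, pp,
                  prominence_mm = config$prominence_mm)
      }, error = function(e) e)
      if (inherits(tip, "error")) {
        rows[[length(rows)]]$flag <- paste0(
          r$flag, ifelse(nzchar(r$flag), ";", ""), "cusp_not_found")
      } else {
        tips[[length(tips) + 1L]] <- tibble::tibble(
          side = sd, pos = pp, x = tip$buccal[1], y = tip$buccal[2],
          z = tip$buccal[3])
      }
    }
  }
  teeth <- dplyr::bind_rows(rows)
  tips_tb <- dplyr::bind_rows(tips)
  aw <- if (nrow(tips_tb)) arch_widths(tips_tb) else
    tibble::tibble(parameter = character(), width_mm = numeric())
  structure(list(
    teeth = teeth, arch_widths = aw, cusp_tips = tips_tb,
    provenance = list(kind = "scan", R = config$frnn_radius,
                      cell_mm = config$depth_cell_mm,
                      midline = config$midline,
                      runtime_s = as.numeric(difftime(Sys.time(), t0, "secs")))),
    class = "measurement_report")
}

#' Write a measurement report as JSON
#'
#' Serializes the per-tooth table, arch widths and provenance of a
#' `measurement_report` to a machine-readable JSON file.
#'
#' @param report a `measurement_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "measurement_report"))
  out <- list(kind = report$provenance$kind, teeth = report$teeth,
              arch_widths = report$arch_widths,
              separation = report$separation,
              provenance = report$provenance)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a key-value YAML file whose keys are [pipeline_config()] argument
#' names; unknown keys are rejected by the constructor.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("<measurement_report> %s: %d teeth measured\n",
              x$provenance$kind, sum(!is.na(x$teeth$width_mm))))
  print(x$teeth[, intersect(c("jaw", "side", "pos", "width_mm", "flag"),
                            names(x$teeth))], n = 24)
  if (!is.null(x$arch_widths) && nrow(x$arch_widths)) {
    cat("arch widths:\n"); print(x$arch_widths)
  }
  invisible(x)
}

#' Match measured teeth to phantom ground truth
#'
#' Matches each true tooth to the nearest measured landmark-pair midpoint in
#' the (x, y) mm plane and reports, per tooth, the identification
#' correctness and width error. The identification accuracy over matched
#' teeth and the width MAE follow.
#'
#' @param report a `measurement_report`.
#' @param truth a `phantom_truth`.
#' @param jaw restrict to one jaw (scan runs measure a single arch).
#' @param max_dist_mm maximum center distance for a match.
#' @return tibble with one row per true tooth: truth ids, matched
#'   measurement, `fdi_correct`, `width_err_mm`.
#' @export
match_to_truth <- function(report, truth, jaw = NULL, max_dist_mm = 4) {
  tt <- truth$teeth
  if (!is.null(truth$alpha_deg) && truth$alpha_deg != 0 &&
      !is.null(truth$pivot)) {
    # measurements are made in the aligned frame; bring the truth there
    R <- rot3_x(-truth$alpha_deg)
    unrot <- function(px, py, pz) {
      p <- sweep(cbind(px, py, pz), 2, truth$pivot) %*% t(R)
      sweep(p, 2, truth$pivot, "+")
    }
    for (pre in c("mes", "dis", "tipb", "tipl")) {
      cols <- paste0(pre, c("_x", "_y", "_z"))
      if (all(cols %in% names(tt))) {
        u <- unrot(tt[[cols[1]]], tt[[cols[2]]], tt[[cols[3]]])
        tt[[cols[1]]] <- u[, 1]; tt[[cols[2]]] <- u[, 2]; tt[[cols[3]]] <- u[, 3]
      }
    }
  }
  if (!is.null(jaw)) tt <- tt[tt$jaw == jaw, ]
  mt <- report$teeth
  mt$mid_x <- (mt$mes_x + mt$dis_x) / 2
  mt$mid_y <- (mt$mes_y + mt$dis_y) / 2
  rows <- list()
  for (i in seq_len(nrow(tt))) {
    tr <- tt[i, ]
    cand <- mt
    if (!is.null(jaw) || !"jaw" %in% names(mt) || all(is.na(mt$jaw))) {
    } else cand <- mt[mt$jaw == tr$jaw, ]
    tcx <- (tr$mes_x + tr$dis_x) / 2; tcy <- (tr$mes_y + tr$dis_y) / 2
    d <- sqrt((cand$mid_x - tcx)^2 + (cand$mid_y - tcy)^2)
    j <- which.min(d)
    matched <- length(j) == 1 && is.finite(d[j]) && d[j] <= max_dist_mm
    rows[[i]] <- tibble::tibble(
      tooth = tr$tooth, jaw = tr$jaw, side = tr$side, pos = tr$pos,
      truth_mm = tr$width_mm,
      matched = matched,
      meas_side = if (matched) cand$side[j] else NA_character_,
      meas_pos = if (matched) cand$pos[j] else NA_integer_,
      width_mm = if (matched) cand$width_mm[j] else NA_real_,
      flag = if (matched) cand$flag[j] else "unmatched",
      fdi_correct = matched && identical(cand$side[j], tr$side) &&
        isTRUE(cand$pos[j] == tr$pos),
      width_err_mm = if (matched) abs(cand$width_mm[j] - tr$width_mm)
                     else NA_real_)
  }
  dplyr::bind_rows(rows)
}
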