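#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_path geom_point
#'   geom_hline geom_line geom_text scale_fill_gradient coord_fixed labs
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

as_raster_df <- function(m) {
  tibble::tibble(x = rep(seq_len(nrow(m)), times = ncol(m)),
                 y = rep(seq_len(ncol(m)), each = nrow(m)),
                 intensity = as.numeric(m))
}

#' Plot a panoramic image
#'
#' @param object a `panoramic_image`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.panoramic_image <- function(object, ...) {
  df <- as_raster_df(object$data)
  ggplot(df, aes(x, y, fill = intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", na.value = "black") +
    coord_fixed() +
    labs(x = "arch position c", y = "axial z",
         title = "Panoramic reprojection") +
    theme_minimal()
}

#' Plot a MIP with numbered detections and midline
#'
#' @param object a `mip_image`.
#' @param detections optional numbered `tooth_detections` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mip_image <- function(object, detections = NULL, ...) {
  p <- ggplot(as_raster_df(object$data), aes(x, y)) +
    geom_raster(aes(fill = intensity)) +
    scale_fill_gradient(low = "black", high = "white") +
    coord_fixed() +
    labs(x = "x (lateral)", y = "y (antero-posterior)",
         title = sprintf("MIP (%s jaw)", object$jaw)) +
    theme_minimal()
  if (!is.null(detections)) {
    det <- detections$detections
    lab <- ifelse(is.na(det$pos), "?", paste0(det$side, det$pos))
    p <- p + geom_text(data = tibble::tibble(x = det$cx, y = det$cy, l = lab),
                       aes(x, y, label = l), color = "red", inherit.aes = FALSE)
    prof <- detections$profile
    if (!is.null(prof)) {
      p <- p + geom_path(data = tibble::tibble(x = prof$boundary[, 1],
                                               y = prof$boundary[, 2]),
                         aes(x, y), color = "cyan", inherit.aes = FALSE)
      if (!is.null(prof$p_mid))
        p <- p + geom_point(data = tibble::tibble(x = prof$p_mid[1],
                                                  y = prof$p_mid[2]),
                            aes(x, y), color = "yellow", size = 3,
                            inherit.aes = FALSE)
    }
  }
  p
}

#' Bland--Altman plot
#'
#' @param object a `bland_altman` fit.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$data, aes(mean_mm, diff_mm)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = object$mean_diff, color = "red") +
    geom_hline(yintercept = c(object$lower, object$upper), color = "blue",
               linetype = "dashed") +
    labs(x = "mean of methods (mm)", y = "difference (mm)",
         title = "Bland-Altman agreement") +
    theme_minimal()
}

#' Success-rate curve plot
#'
#' @param object a `success_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.success_curve <- function(object, ...) {
  ggplot(object, aes(threshold, fraction)) +
    geom_line() +
    labs(x = "threshold (mm)", y = "success rate",
         title = "Success rate vs error threshold") +
    theme_minimal()
}

#' Export a matrix as a debug PNG
#'
#' Writes a grayscale PNG of any 2D image (projection, panoramic, MIP) for
#' visual inspection; intensities are rescaled to \[0, 1\].
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_debug_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for debug export")
  m <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
  rng <- range(m, finite = TRUE)
  m <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  m[!is.finite(m)] <- 0
  png::writePNG(m, path)
  invisible(path)
}
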