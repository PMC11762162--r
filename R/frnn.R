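#' Fixed-radius nearest-neighbor gravitational color classifier
#'
#' Builds the FRNN model that separates teeth from gum by color. Training
#' samples are HSV triples with labels 1 (teeth) and 2 (gum); candidate
#' selection takes every training sample within radius `R` of the query in
#' HSV space, where the distance is Euclidean over
#' `(dh_circ, ds, dv)` with circular hue distance
#' `dh_circ = min(|dh|, 1 - |dh|)`. The decision statistic is an
#' inverse-square "gravity" sum with signed contributions: teeth samples
#' attract with sign -1 and gum samples with sign +1, so a negative total
#' force classifies the query as teeth and the tie (including an empty
#' candidate set) goes to gum.
#'
#' @param samples data frame or matrix with columns `h`, `s`, `v` and
#'   (data frame) `label`, or pass `label` separately.
#' @param label integer vector in \{1, 2\} (1 teeth, 2 gum) when `samples`
#'   has no label column.
#' @param R candidate radius in HSV units.
#' @param eps minimum-distance floor guarding the inverse square at exact
#'   color matches.
#' @return object of class `frnn_model`.
#' @export
frnn_model <- function(samples, label = NULL, R = 0.15, eps = 1e-6) {
  if (is.data.frame(samples)) {
    label <- label %||% samples$label
    samples <- as.matrix(samples[, c("h", "s", "v")])
  } else samples <- as.matrix(samples)
  label <- as.integer(label)
  if (is.null(label) || length(label) != nrow(samples))
    stop("a label per training sample is required")
  if (!all(label %in% c(1L, 2L))) stop("labels must be 1 (teeth) or 2 (gum)")
  if (!any(label == 1L) || !any(label == 2L))
    stop("training set must contain both labels")
  if (R <= 0 || eps <= 0) stop("R and eps must be positive")
  structure(list(samples = samples, label = label, R = R, eps = eps,
                 sign = c(-1, 1)),  # sigma(1) = -1 teeth, sigma(2) = +1 gum
            class = "frnn_model")
}

#' @export
print.frnn_model <- function(x, ...) {
  cat(sprintf("<frnn_model> %d samples (%d teeth / %d gum), R = %g\n",
              nrow(x$samples), sum(x$label == 1L), sum(x$label == 2L), x$R))
  invisible(x)
}

# circular-hue Euclidean color distances from one query to all samples
hsv_distance <- function(query, samples) {
  dh <- abs(samples[, 1] - query[1])
  dh <- pmin(dh, 1 - dh)
  sqrt(dh^2 + (samples[, 2] - query[2])^2 + (samples[, 3] - query[3])^2)
}

#' FRNN candidate set for a query color
#'
#' Exactly the training samples at color distance `< R` from the query.
#'
#' @param model an [frnn_model].
#' @param query HSV triple.
#' @return tibble of candidates: `h`, `s`, `v`, `label`, `d` (may be empty).
#' @export
frnn_candidates <- function(model, query) {
  stopifnot(inherits(model, "frnn_model"))
  d <- hsv_distance(as.numeric(query), model$samples)
  sel <- d < model$R
  tibble::tibble(h = model$samples[sel, 1], s = model$samples[sel, 2],
                 v = model$samples[sel, 3], label = model$label[sel],
                 d = d[sel])
}

#' Gravity score of a query against its candidates
#'
#' `F = sum sigma(label_k) / max(d_k, eps)^2`; an empty candidate set gives
#' `F = 0`.
#'
#' @param model an [frnn_model].
#' @param candidates tibble from [frnn_candidates()].
#' @return the signed force F.
#' @export
gravity_score <- function(model, candidates) {
  if (nrow(candidates) == 0) return(0)
  sum(model$sign[candidates$label] / pmax(candidates$d, model$eps)^2)
}

#' Classify colors as teeth or gum
#'
#' Applies the FRNN gravity rule to one or many HSV queries: `F < 0` gives
#' label 1 (teeth); `F >= 0` -- including the empty-candidate tie -- gives
#' label 2 (gum).
#'
#' @param model an [frnn_model].
#' @param query HSV triple, or an n x 3 matrix / data frame of queries.
#' @return integer label(s) in \{1, 2\}.
#' @export
classify_point <- function(model, query) {
  q <- if (is.data.frame(query)) as.matrix(query[, c("h", "s", "v")])
       else if (is.null(dim(query))) matrix(as.numeric(query), ncol = 3)
       else as.matrix(query)
  vapply(seq_len(nrow(q)), function(i) {
    d <- hsv_distance(q[i, ], model$samples)
    sel <- d < model$R
    if (!any(sel)) return(2L)
    f <- sum(model$sign[model$label[sel]] / pmax(d[sel], model$eps)^2)
    if (f < 0) 1L else 2L
  }, integer(1))
}

#' Teeth-only cloud and its axial depth map
#'
#' Classifies every point of a colored scan cloud, keeps the teeth points,
#' removes specks by dropping small planar connected clusters, and
#' rasterizes the maximum z per (x, y) grid cell into a depth map with a
#' validity mask.
#'
#' @param cloud a [colored_cloud].
#' @param model an [frnn_model].
#' @param cell_mm depth-map grid resolution in mm.
#' @param min_cluster_cells planar clusters covering fewer grid cells than
#'   this are discarded as specks.
#' @return list with `teeth` (the teeth-only [colored_cloud]) and `depth`
#'   (a [depth_map] in mm units).
#' @export
teeth_cloud_and_depthmap <- function(cloud, model, cell_mm = 0.25,
                                     min_cluster_cells = 40L) {
  stopifnot(inherits(cloud, "colored_cloud"), inherits(model, "frnn_model"))
  lab <- classify_point(model, cloud)
  teeth <- cloud[lab == 1L, ]
  if (nrow(teeth) == 0) stop("no teeth detected in the scan cloud")
  dm <- rasterize_depth(teeth$x, teeth$y, teeth$z, cell_mm)
  # speck removal on the occupancy grid
  cc <- EBImage::bwlabel(dm$valid)
  sizes <- tabulate(as.integer(cc))
  keep_lab <- which(sizes >= min_cluster_cells)
  if (!length(keep_lab)) stop("no teeth detected: all clusters below minimum size")
  keep_cell <- matrix(as.integer(cc) %in% keep_lab, nrow(dm$z))
  dm$valid <- dm$valid & keep_cell
  dm$z[!dm$valid] <- NA_real_
  # drop the corresponding points
  i <- pmin(pmax(ceiling((teeth$x - dm$origin[1]) / dm$spacing[1]), 1L),
            nrow(dm$z))
  j <- pmin(pmax(ceiling((teeth$y - dm$origin[2]) / dm$spacing[2]), 1L),
            ncol(dm$z))
  pt_keep <- dm$valid[cbind(i, j)]
  teeth <- teeth[pt_keep, ]
  list(teeth = teeth, depth = dm)
}
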