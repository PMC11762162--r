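#' Colored point cloud container
#'
#' A tibble-backed point cloud: columns `x`, `y`, `z` (mm), `h`, `s`, `v`
#' (HSV color; hue on the circular unit interval \[0, 1), saturation and
#' value in \[0, 1\]), and optionally an integer `label` column.
#'
#' @param points numeric matrix/data frame with columns x, y, z (mm).
#' @param colors_hsv numeric matrix/data frame with columns h, s, v.
#' @param label optional integer per-point label.
#' @return a tibble of class `colored_cloud`.
#' @export
colored_cloud <- function(points, colors_hsv, label = NULL) {
  points <- unname(as.matrix(points))
  colors_hsv <- unname(as.matrix(colors_hsv))
  if (nrow(points) != nrow(colors_hsv))
    stop("points and colors must have the same length")
  h <- colors_hsv[, 1]; s <- colors_hsv[, 2]; v <- colors_hsv[, 3]
  if (any(h < 0 | h >= 1 | s < -1e-9 | s > 1 + 1e-9 | v < -1e-9 | v > 1 + 1e-9))
    stop("HSV channels out of range: h in [0,1), s and v in [0,1]")
  out <- tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3],
                        h = h, s = clamp(s, 0, 1), v = clamp(v, 0, 1))
  if (!is.null(label)) out$label <- as.integer(label)
  class(out) <- c("colored_cloud", class(out))
  out
}

#' RGB to HSV on unit ranges
#'
#' 8-bit RGB triples to HSV with hue on \[0, 1) (circular), saturation and
#' value in \[0, 1\]. Hue of an achromatic color (s = 0) is reported as 0.
#'
#' @param rgb numeric matrix n x 3 with channels in 0..255.
#' @return numeric matrix n x 3 with columns h, s, v.
#' @export
rgb255_to_hsv <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  hsv[, 1] <- hsv[, 1] %% 1
  colnames(hsv) <- c("h", "s", "v")
  hsv
}

#' HSV (unit ranges) back to 8-bit RGB
#'
#' @param hsv numeric matrix n x 3, h in \[0,1), s and v in \[0,1\].
#' @return integer matrix n x 3 with channels 0..255.
#' @export
hsv_to_rgb255 <- function(hsv) {
  hsv <- matrix(as.numeric(hsv), ncol = 3)
  cols <- grDevices::hsv(hsv[, 1] %% 1, clamp(hsv[, 2], 0, 1),
                         clamp(hsv[, 3], 0, 1))
  out <- t(grDevices::col2rgb(cols))
  colnames(out) <- c("r", "g", "b")
  out
}

#' Read a colored PLY point cloud
#'
#' Reads vertices with per-vertex 8-bit RGB color from a PLY file (ASCII or
#' binary little-endian). Colors are converted to HSV unit ranges; vertex
#' order is preserved. Faces, if present, are ignored: only the vertex
#' element is consumed.
#'
#' @param path PLY file path.
#' @return a [colored_cloud].
#' @export
load_colored_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readLines(con, n = 1L) != "ply") stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NULL
  props <- character()
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("PLY header ended without end_header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    }
    if (tok[1] == "property" && in_vertex) {
      props <- c(props, paste(tok[2], tok[3]))
    }
    if (tok[1] == "end_header") break
  }
  if (is.null(nvert)) stop("PLY file has no vertex element")
  pnames <- sub("^\\S+ ", "", props)
  ptypes <- sub(" \\S+$", "", props)
  need <- c("x", "y", "z", "red", "green", "blue")
  if (!all(c("red", "green", "blue") %in% pnames))
    stop("PLY vertices carry no color: per-vertex uchar red/green/blue ",
         "properties are required (property uchar red ...)")
  if (!all(c("x", "y", "z") %in% pnames)) stop("PLY vertex layout lacks x/y/z")
  sizes <- c("float" = 4L, "float32" = 4L, "double" = 8L, "float64" = 8L,
             "uchar" = 1L, "uint8" = 1L, "char" = 1L, "int8" = 1L,
             "short" = 2L, "ushort" = 2L, "int16" = 2L, "uint16" = 2L,
             "int" = 4L, "uint" = 4L, "int32" = 4L, "uint32" = 4L)
  if (identical(fmt, "ascii")) {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))][seq_len(nvert)]
    m <- do.call(rbind, lapply(strsplit(trimws(rest), "\\s+"),
                               function(t) as.numeric(t[seq_along(pnames)])))
  } else if (identical(fmt, "binary_little_endian")) {
    m <- matrix(NA_real_, nvert, length(pnames))
    widths <- sizes[ptypes]
    if (anyNA(widths)) stop("unsupported PLY property type")
    rowbytes <- sum(widths)
    buf <- readBin(con, "raw", nvert * rowbytes)
    offs <- cumsum(c(0L, widths))[seq_along(widths)]
    base <- (seq_len(nvert) - 1L) * rowbytes
    for (p in seq_along(pnames)) {
      idx <- as.vector(outer(seq_len(widths[p]), base + offs[p], "+"))
      col_raw <- buf[idx]
      m[, p] <- switch(as.integer(widths[p]),
        as.numeric(col_raw),                                    # 1 byte
        readBin(col_raw, "integer", nvert, 2L, endian = "little"),
        stop("unsupported width"),
        if (ptypes[p] %in% c("float", "float32"))
          readBin(col_raw, "numeric", nvert, 4L, endian = "little")
        else readBin(col_raw, "integer", nvert, 4L, endian = "little"),
        NULL, NULL, NULL,
        readBin(col_raw, "numeric", nvert, 8L, endian = "little"))
    }
  } else {
    stop("unsupported PLY format: ", fmt)
  }
  colnames(m) <- pnames
  hsv <- rgb255_to_hsv(m[, c("red", "green", "blue"), drop = FALSE])
  colored_cloud(m[, c("x", "y", "z"), drop = FALSE], hsv)
}

#' Write a colored point cloud to PLY
#'
#' @param cloud a [colored_cloud]; HSV colors are converted back to 8-bit RGB.
#' @param path output path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_colored_mesh <- function(cloud, path,
                               format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  n <- nrow(cloud)
  rgb <- hsv_to_rgb255(cbind(cloud$h, cloud$s, cloud$v))
  hdr <- c("ply", paste("format", format, "1.0"),
           "comment generated by odontometry",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (format == "ascii") {
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d", cloud$x, cloud$y, cloud$z,
                       rgb[, 1], rgb[, 2], rgb[, 3]), con, sep = "\n")
  } else {
    xyz <- writeBin(as.numeric(rbind(cloud$x, cloud$y, cloud$z)), raw(),
                    size = 4L, endian = "little")
    xyz <- matrix(xyz, nrow = 12L)
    col <- matrix(as.raw(t(rgb)), nrow = 3L)
    writeBin(as.vector(rbind(xyz, col)), con)
  }
  invisible(path)
}
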