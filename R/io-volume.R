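#' Read a voxel volume from NRRD or NIfTI
#'
#' NIfTI-1 files (`.nii`, `.nii.gz`) are read through RNifti; NRRD files
#' through a bundled reader for attached-data NRRD (raw or gzip encodings,
#' little-endian). The voxel spacing is taken from `pixdim` (NIfTI) or from
#' `spacings`/`space directions` (NRRD); a file without usable spacing
#' metadata, or with non-positive spacing, is a hard error naming the field.
#'
#' @param path file path; format chosen by extension.
#' @return a [voxel_volume].
#' @seealso [write_volume()]
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd_volume(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
    sp <- RNifti::niftiHeader(img)$pixdim[2:4]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("NIfTI field `pixdim` has non-positive spacing")
    voxel_volume(array(as.numeric(img), dim(img)), spacing = sp,
                 origin = c(0, 0, 0))
  } else {
    stop("unsupported volume format (expected .nrrd, .nii or .nii.gz): ", path)
  }
}

#' Write a voxel volume to NRRD or NIfTI
#'
#' @param volume a [voxel_volume].
#' @param path output path; `.nrrd` or `.nii`/`.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_volume(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

# ---- NRRD (attached data, NRRD0004) ----------------------------------------

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("NRRD header ended without a blank line")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) hdr[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(key) {
    if (is.null(hdr[[key]])) stop("NRRD header missing field `", key, "`")
    hdr[[key]]
  }
  dims <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (as.integer(need("dimension")) != 3L || length(dims) != 3L)
    stop("NRRD field `dimension` must be 3")
  spacing <- if (!is.null(hdr[["spacings"]])) {
    as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    vapply(vecs, function(v) {
      sqrt(sum(as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])^2))
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    stop("NRRD header has neither `spacings` nor `space directions`")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD field `spacings` must give three positive values")
  origin <- if (!is.null(hdr[["space origin"]])) {
    as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]), ",")[[1]])
  } else c(0, 0, 0)
  type <- need("type")
  enc <- tolower(need("encoding"))
  n <- prod(dims)
  read_payload <- function(rcon) {
    switch(type,
      "float" = readBin(rcon, "numeric", n, size = 4L, endian = "little"),
      "double" = readBin(rcon, "numeric", n, size = 8L, endian = "little"),
      "short" = , "int16" = readBin(rcon, "integer", n, size = 2L,
                                    signed = TRUE, endian = "little"),
      "unsigned short" = , "uint16" = readBin(rcon, "integer", n, size = 2L,
                                              signed = FALSE, endian = "little"),
      "int" = , "int32" = readBin(rcon, "integer", n, size = 4L,
                                  endian = "little"),
      "uchar" = , "uint8" = as.integer(readBin(rcon, "raw", n)),
      stop("unsupported NRRD field `type`: ", type))
  }
  vals <- if (enc == "raw") {
    read_payload(con)
  } else if (enc %in% c("gz", "gzip")) {
    payload <- readBin(con, "raw", file.info(path)$size)
    read_payload(rawConnection(memDecompress(payload, type = "gzip")))
  } else stop("unsupported NRRD field `encoding`: ", enc)
  if (length(vals) != n) stop("NRRD payload truncated")
  voxel_volume(array(as.numeric(vals), dims), spacing = spacing,
               origin = origin)
}

write_nrrd_volume <- function(volume, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  d <- dim(volume$data)
  hdr <- c(
    "NRRD0004",
    "# generated by odontometry",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.17g %.17g %.17g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    sprintf("encoding: %s", encoding),
    "endian: little",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.numeric(volume$data), raw(), size = 8L,
                      endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}
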