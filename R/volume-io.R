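# Volume input/output: multi-page TIFF, MRC2014, raw + JSON sidecar.
#
# Round-trip fidelity contract: integer-valued data written in any of the
# three formats reads back bit-identically, and the GridSpec (voxel size,
# origin offset) survives via the format's own metadata or the JSON
# sidecar written next to the file.

sidecarPath <- function(path) paste0(path, ".json")

writeSidecar <- function(path, vol, dtype = NULL) {
  meta <- list(shape = gridShape(vol), voxel_size_nm = voxelSize(vol),
               origin = vol@grid@origin, semantics = semantics(vol),
               axis_order = "y,x,z")
  if (!is.null(dtype)) meta$dtype <- dtype
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a volume to disk
#'
#' Formats: `"tiff"` (multi-page, 8-bit for binary, 16-bit for grayscale
#' and labels), `"mrc"` (MRC2014, mode 2 float32 or mode 1 int16), and
#' `"raw"` (native binary + mandatory JSON sidecar). All formats also get
#' a JSON sidecar carrying the grid metadata, because TIFF has no portable
#' voxel-size tag.
#'
#' @param volume a [VoxelVolume-class]
#' @param path output file path
#' @param format "tiff", "mrc" or "raw"
#' @return `path`, invisibly
#' @export
writeVolume <- function(volume, path, format = c("tiff", "mrc", "raw")) {
  format <- match.arg(format)
  stopifnot(is(volume, "VoxelVolume"))
  a <- voxelData(volume)
  if (format == "tiff") {
    if (semantics(volume) == "binary") {
      pages <- lapply(seq_len(dim(a)[3]), function(k)
        matrix(as.numeric(a[, , k]), dim(a)[1], dim(a)[2]))
      tiff::writeTIFF(pages, path, bits.per.sample = 8L)
      writeSidecar(path, volume, dtype = "uint8")
    } else {
      mx <- max(a)
      if (min(a) < 0 || mx > 65535)
        stop("16-bit TIFF requires values in [0, 65535]; rescale first",
             call. = FALSE)
      pages <- lapply(seq_len(dim(a)[3]), function(k)
        matrix(a[, , k] / 65535, dim(a)[1], dim(a)[2]))
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
      writeSidecar(path, volume, dtype = "uint16")
    }
  } else if (format == "mrc") {
    writeMRC(volume, path)
    writeSidecar(path, volume)
  } else {
    dtype <- if (semantics(volume) == "binary") "uint8"
      else if (is.integer(a)) "int32" else "float64"
    con <- file(path, "wb")
    on.exit(close(con))
    if (dtype == "uint8") {
      writeBin(as.raw(as.integer(a)), con)
    } else if (dtype == "int32") {
      writeBin(as.vector(a), con, size = 4L, endian = "little")
    } else {
      writeBin(as.vector(as.numeric(a)), con, size = 8L, endian = "little")
    }
    writeSidecar(path, volume, dtype = dtype)
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' @param path input file
#' @param format "tiff", "mrc" or "raw"; guessed from the extension when
#'   missing
#' @param voxelSize voxel edge (nm); overrides metadata. TIFF stacks and
#'   raw files without a sidecar or explicit value are rejected rather
#'   than silently defaulting.
#' @return a [VoxelVolume-class] (or [BinaryVolume-class] /
#'   [LabeledVolume-class] when the sidecar records those semantics)
#' @export
readVolume <- function(path, format = NULL, voxelSize = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(sub(".*\\.", "", basename(path))),
                     tif = , tiff = "tiff", mrc = , rec = "mrc", "raw")
  }
  meta <- readSidecar(path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]])[1:2], length(pages))
    a <- array(0, d)
    for (k in seq_along(pages)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      a[, , k] <- pg
    }
    h <- voxelSize %||% meta$voxel_size_nm
    if (is.null(h))
      stop("TIFF carries no voxel size: pass voxelSize= or provide a sidecar",
           call. = FALSE)
    sem <- meta$semantics %||% "grayscale"
    if (identical(meta$dtype, "uint8")) a <- round(a * 255)
    if (identical(meta$dtype, "uint16")) a <- round(a * 65535)
    org <- as.integer(meta$origin %||% c(0L, 0L, 0L))
    if (sem == "binary") return(BinaryVolume(a > 0, h, origin = org))
    if (sem == "labels")
      return(LabeledVolume(array(as.integer(a), d), h, origin = org))
    return(VoxelVolume(a, h, "grayscale", origin = org))
  }
  if (format == "mrc") {
    vol <- readMRC(path, voxelSize = voxelSize)
    if (!is.null(meta$semantics) && meta$semantics == "binary")
      vol <- BinaryVolume(voxelData(vol) > 0, voxelSize(vol),
                          origin = as.integer(meta$origin %||% c(0L, 0L, 0L)))
    return(vol)
  }
  # raw + sidecar
  if (is.null(meta))
    stop("raw volume requires a JSON sidecar (shape, dtype, voxel_size_nm)",
         call. = FALSE)
  for (field in c("shape", "dtype", "voxel_size_nm"))
    if (is.null(meta[[field]]))
      stop("raw sidecar is missing required field: ", field, call. = FALSE)
  d <- as.integer(meta$shape)
  n <- prod(d)
  bytes <- file.size(path)
  expect <- n * switch(meta$dtype, uint8 = 1, int32 = 4, float64 = 8,
                       stop("unsupported raw dtype: ", meta$dtype,
                            call. = FALSE))
  if (bytes != expect)
    stop(sprintf("raw file size (%d bytes) does not match sidecar shape (expected %d)",
                 bytes, expect), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(meta$dtype,
    uint8 = as.integer(readBin(con, "raw", n)),
    int32 = readBin(con, "integer", n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n, size = 8L, endian = "little"))
  h <- voxelSize %||% meta$voxel_size_nm
  org <- as.integer(meta$origin %||% c(0L, 0L, 0L))
  sem <- meta$semantics %||% "grayscale"
  if (sem == "binary") return(BinaryVolume(array(vals > 0, d), h, origin = org))
  if (sem == "labels") return(LabeledVolume(array(as.integer(vals), d), h,
                                            origin = org))
  VoxelVolume(array(vals, d), h, "grayscale", origin = org)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal MRC2014 support (mode 1 int16 / mode 2 float32) ----
# 1024-byte header; voxel size stored as cell dimension / extent, in
# Angstrom (1 nm = 10 A). Data written x-fastest to follow the standard,
# i.e. the in-memory (y, x, z) array is transposed per section on the way
# out and back in.

writeMRC <- function(volume, path) {
  a <- voxelData(volume)
  d <- dim(a)  # (y, x, z)
  intish <- (is.integer(a) || is.logical(a)) &&
    max(a) <= 32767 && min(a) >= -32768
  mode <- if (intish) 1L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(d[2], d[1], d[3]))              # nx, ny, nz
  wi(mode)                             # mode
  wi(c(0, 0, 0))                       # nxstart..
  wi(c(d[2], d[1], d[3]))              # mx, my, mz
  wf(c(d[2], d[1], d[3]) * voxelSize(volume) * 10)  # cella (A)
  wf(c(90, 90, 90))                    # cellb
  wi(c(1, 2, 3))                       # mapc, mapr, maps
  wf(c(min(a), max(a), mean(a)))       # dmin, dmax, dmean
  wi(0)                                # ispg
  wi(0)                                # nsymbt
  writeBin(raw(100), con)              # extra
  wf(c(0, 0, 0))                       # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(0)                                # rms
  wi(0)                                # nlabl
  writeBin(raw(800), con)              # labels
  for (k in seq_len(d[3])) {
    sec <- t(a[, , k])                 # x fastest
    if (mode == 1L) writeBin(as.integer(sec), con, size = 2L,
                             endian = "little")
    else writeBin(as.numeric(sec), con, size = 4L, endian = "little")
  }
  invisible(path)
}

readMRC <- function(path, voxelSize = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "double", n, size = 4L, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  ri(3); mxyz <- ri(3)
  cella <- rf(3)
  seek(con, 1024)
  d <- c(nxyz[2], nxyz[1], nxyz[3])  # (y, x, z)
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    `0` = as.integer(readBin(con, "raw", n)),
    `1` = readBin(con, "integer", n, size = 2L, endian = "little"),
    `2` = readBin(con, "double", n, size = 4L, endian = "little"),
    stop("unsupported MRC mode: ", mode, call. = FALSE))
  if (length(vals) != n) stop("MRC data truncated", call. = FALSE)
  a <- array(0, d)
  per <- nxyz[1] * nxyz[2]
  for (k in seq_len(d[3])) {
    sec <- matrix(vals[((k - 1) * per + 1):(k * per)], nxyz[1], nxyz[2])
    a[, , k] <- t(sec)
  }
  h <- voxelSize %||% (if (all(cella > 0) && all(mxyz > 0))
    cella[1] / mxyz[1] / 10 else NULL)
  if (is.null(h)) stop("MRC header has no voxel size; pass voxelSize=",
                       call. = FALSE)
  if (mode %in% c(0, 1)) a <- array(as.integer(a), d)
  VoxelVolume(a, h, "grayscale")
}

#' Extract a subvolume
#'
#' 0-based, half-open index windows: `lower` is the 0-based corner and
#' `extent` the window size, so the crop covers voxels
#' `lower + 1 .. lower + extent` in 1-based R indexing. The output grid
#' records the accumulated offset so provenance survives repeated crops.
#'
#' @param volume a [VoxelVolume-class]
#' @param lower integer(3), 0-based lower corner (y, x, z)
#' @param extent integer(3), window extents
#' @return a volume of the same class
#' @export
cropSubvolume <- function(volume, lower, extent) {
  stopifnot(is(volume, "VoxelVolume"))
  lower <- as.integer(lower); extent <- as.integer(extent)
  d <- gridShape(volume)
  if (any(lower < 0L) || any(extent < 1L) || any(lower + extent > d))
    stop(sprintf("crop window [%s]+[%s] outside volume extents [%s]",
                 paste(lower, collapse = ","),
                 paste(extent, collapse = ","),
                 paste(d, collapse = ",")), call. = FALSE)
  a <- voxelData(volume)[lower[1] + seq_len(extent[1]),
                         lower[2] + seq_len(extent[2]),
                         lower[3] + seq_len(extent[3]), drop = FALSE]
  org <- volume@grid@origin + lower
  if (is(volume, "BinaryVolume"))
    BinaryVolume(a, voxelSize(volume), origin = org)
  else if (is(volume, "LabeledVolume"))
    LabeledVolume(a, voxelSize(volume), nLabels = nLabels(volume),
                  origin = org)
  else
    VoxelVolume(a, voxelSize(volume), semantics(volume), origin = org)
}
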