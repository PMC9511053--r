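# Minimal baseline TIFF 6.0 I/O: little-endian, uncompressed, single-channel
# 32-bit IEEE float, one strip per page. No TIFF-capable package exists in
# the supported environment, so the subset needed for this package's own
# files is implemented here; the reader rejects anything else explicitly.
# Physical metadata never goes into TIFF tags: it lives in a YAML sidecar so
# that it is human-auditable and survives tools that strip tags.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_bytes = 279L, sample_format = 339L)

#' Write a multi-page TIFF
#'
#' Pages are written as uncompressed 32-bit IEEE float, grayscale,
#' little-endian — one page per frame (time series) or per z-plane (stack).
#'
#' @param pages 3D array `[ny, nx, n_pages]` or a list of matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path) {
  if (is.array(pages) && length(dim(pages)) == 3) {
    pages <- lapply(seq_len(dim(pages)[3]), function(k) pages[, , k])
  }
  if (!is.list(pages) || !all(vapply(pages, is.matrix, TRUE)))
    stop("'pages' must be a 3D array or list of matrices")
  np <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  page_bytes <- 4L * nx * ny
  n_entries <- length(TIFF_TAGS)
  ifd_bytes <- 2L + n_entries * 12L + 4L
  data_off <- 8L + (seq_len(np) - 1L) * page_bytes
  ifd_off <- 8L + np * page_bytes + (seq_len(np) - 1L) * ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (k in seq_len(np)) {
    m <- pages[[k]]
    if (nrow(m) != ny || ncol(m) != nx) stop("all pages must share one size")
    # TIFF rows are stored top to bottom; R matrices are column-major
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(np)) {
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    entry(256L, 3L, 1L, nx)
    entry(257L, 3L, 1L, ny)
    entry(258L, 3L, 1L, 32L)
    entry(259L, 3L, 1L, 1L)            # no compression
    entry(262L, 3L, 1L, 1L)            # BlackIsZero
    entry(273L, 4L, 1L, data_off[k])
    entry(278L, 3L, 1L, ny)            # one strip per page
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, 3L)            # IEEE float
    next_off <- if (k < np) ifd_off[k + 1] else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff()]
#'
#' Supports the baseline subset this package writes (little-endian,
#' uncompressed, grayscale float32, one strip per page) and errors with the
#' offending field name on anything else.
#'
#' @param path TIFF file path.
#' @return 3D array `[ny, nx, n_pages]`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    b <- as.numeric(raw[off + 1:4])
    b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  }
  if (rawToChar(raw[1:2]) != "II")
    stop("unsupported TIFF: not little-endian ('II')")
  if (u16(2) != 42L) stop("not a TIFF file (bad magic)")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    nent <- u16(ifd)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2)
      val <- if (type == 3L) u16(off + 8) else u32(off + 8)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, name) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop(sprintf("unsupported TIFF: missing tag %s", name))
      v
    }
    if (need(259L, "Compression") != 1L)
      stop("unsupported TIFF: Compression != none")
    if (need(258L, "BitsPerSample") != 32L)
      stop("unsupported TIFF: BitsPerSample != 32")
    if ((tags[["339"]] %||% 1L) != 3L)
      stop("unsupported TIFF: SampleFormat != IEEE float")
    nx <- need(256L, "ImageWidth"); ny <- need(257L, "ImageLength")
    if (need(278L, "RowsPerStrip") < ny)
      stop("unsupported TIFF: multiple strips per page")
    doff <- need(273L, "StripOffsets")
    nbytes <- need(279L, "StripByteCounts")
    if (nbytes != 4 * nx * ny)
      stop("unsupported TIFF: StripByteCounts does not match float32 page")
    vals <- readBin(raw[(doff + 1):(doff + nbytes)], "numeric",
                    n = nx * ny, size = 4, endian = "little")
    pages[[length(pages) + 1]] <- matrix(vals, nrow = ny, ncol = nx,
                                         byrow = TRUE)
    ifd <- u32(ifd + 2 + nent * 12)
  }
  array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                               length(pages)))
}

# ---- sidecar metadata ----

write_sidecar <- function(meta, path) {
  # precision 17 so physical metadata (e.g. a 1/6 s frame interval)
  # round-trips bit-exactly
  yaml::write_yaml(meta, path, precision = 17)
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) stop(sprintf("sidecar not found: %s", path))
  yaml::read_yaml(path)
}

#' Write an image series as TIFF plus YAML sidecar
#'
#' @param series an [image_series()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path minus extension>.yaml`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  write_tiff(series$frames, path)
  write_sidecar(list(kind = "time_series",
                     pixel_size_um = series$pixel_size,
                     frame_interval_s = series$frame_interval,
                     n_frames = dim(series$frames)[3]),
                sidecar_path(path))
  invisible(path)
}

#' Write a z-stack as TIFF plus YAML sidecar
#'
#' @param stack a [vessel_stack()].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "vessel_stack"))
  write_tiff(stack$voxels * 1.0, path)
  write_sidecar(list(kind = "z_stack",
                     voxel_size_um = as.list(stack$voxel_size),
                     depth_um = stack_depth(stack),
                     role = stack$role),
                sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Load an image series from TIFF + sidecar
#'
#' Physical metadata is mandatory: a missing pixel size or frame interval is
#' an error, never a silent default.
#'
#' @param path TIFF path.
#' @param sidecar sidecar YAML path (default: next to `path`).
#' @return An [image_series()].
#' @export
load_series <- function(path, sidecar = sidecar_path(path)) {
  meta <- read_sidecar(sidecar)
  if (!identical(meta$kind, "time_series"))
    stop("sidecar 'kind' is not 'time_series'")
  if (is.null(meta$pixel_size_um)) stop("sidecar missing field: pixel_size_um")
  if (is.null(meta$frame_interval_s))
    stop("sidecar missing field: frame_interval_s")
  frames <- read_tiff(path)
  if (!is.null(meta$n_frames) && meta$n_frames != dim(frames)[3])
    stop(sprintf("sidecar field n_frames (%d) does not match TIFF pages (%d)",
                 meta$n_frames, dim(frames)[3]))
  image_series(frames, meta$pixel_size_um, meta$frame_interval_s)
}

#' Load a z-stack from TIFF + sidecar
#'
#' @inheritParams load_series
#' @return A [vessel_stack()].
#' @export
load_stack <- function(path, sidecar = sidecar_path(path)) {
  meta <- read_sidecar(sidecar)
  if (!identical(meta$kind, "z_stack")) stop("sidecar 'kind' is not 'z_stack'")
  if (is.null(meta$voxel_size_um)) stop("sidecar missing field: voxel_size_um")
  vox <- read_tiff(path)
  vs <- as.numeric(unlist(meta$voxel_size_um))
  if (!is.null(meta$depth_um)) {
    depth <- dim(vox)[3] * vs[3]
    if (abs(depth - meta$depth_um) > 1e-6)
      stop(sprintf(
        "sidecar field depth_um (%g) does not match planes x z-step (%g)",
        meta$depth_um, depth))
  }
  vessel_stack(vox, vs, role = meta$role)
}
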