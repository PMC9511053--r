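#' Time-lapse image series container
#'
#' A 2D+time frame stack with the physical metadata every downstream
#' computation needs: in-plane pixel size (micrometres per pixel) and frame
#' interval (seconds). Pixel `(i, j)` (row, column, 1-based) is centred at
#' physical coordinates `x = (j - 0.5) * pixel_size`,
#' `y = (i - 0.5) * pixel_size`; frame `k` is sampled at
#' `t = (k - 1) * frame_interval`.
#'
#' @param frames numeric array `[ny, nx, n_frames]` of intensities (photons).
#' @param pixel_size in-plane pixel size, um/px.
#' @param frame_interval time between frames, s (1/6 s at the 6 frames/s
#'   acquisition rate used for tracer transit imaging).
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, pixel_size, frame_interval) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("'frames' must be a 3D array [ny, nx, n_frames]")
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_series> %d x %d px (%.3g um/px), %d frames @ %.4g s\n",
    d[1], d[2], x$pixel_size, d[3], x$frame_interval))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$frames)

#' 3D image stack container
#'
#' A z-stack with anisotropic voxel sizes. Voxel `(i, j, k)` (row = y,
#' column = x, plane = z; 1-based) is centred at
#' `((j - 0.5) * dx, (i - 0.5) * dy, (k - 0.5) * dz)`.
#'
#' @param voxels numeric or logical array `[ny, nx, nz]`.
#' @param voxel_size numeric length-3 `(dx, dy, dz)` in um; the acquisition
#'   default is a 1 um z-step over a 120 um depth.
#' @param role optional vessel role label, `"afferent"` or `"efferent"`,
#'   assigned by the annotator from the direction of blood flow (never
#'   inferred by the software).
#' @return An object of class `vessel_stack`.
#' @export
vessel_stack <- function(voxels, voxel_size, role = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("'voxels' must be a 3D array [ny, nx, nz]")
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers (dx, dy, dz) in um")
  if (!is.null(role)) role <- match.arg(role, c("afferent", "efferent"))
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 role = role),
            class = "vessel_stack")
}

#' @export
print.vessel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<vessel_stack> %d x %d x %d voxels (%.3g x %.3g x %.3g um)%s\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    if (is.null(x$role)) "" else paste0(", role: ", x$role)))
  invisible(x)
}

#' @export
dim.vessel_stack <- function(x) dim(x$voxels)

# physical stack depth in um
stack_depth <- function(stack) dim(stack$voxels)[3] * stack$voxel_size[3]
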