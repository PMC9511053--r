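# Semi-automatic proximal tubule tracing. The user supplies ordered seed
# clicks from the glomerulotubular junction outward (click order = flow
# direction); the tracer-filled frame supplies the contrast for refinement.

#' Seed annotation
#'
#' Ordered click points along the tubule, in 0-based pixel coordinates
#' (pixel index i covers physical `[i, i+1) * pixel_size`, centre at
#' `(i + 0.5) * pixel_size`).
#'
#' @param points_px n x 2 matrix of (x, y) pixel coordinates, 0-based.
#' @param image image reference string.
#' @param made_by annotator id.
#' @return A `seed_annotation` object.
#' @export
seed_annotation <- function(points_px, image = "", made_by = "") {
  points_px <- as.matrix(points_px)
  if (nrow(points_px) < 2)
    stop("a seed annotation needs at least 2 points")
  if (ncol(points_px) != 2) stop("'points_px' must be n x 2 (x, y)")
  structure(list(points_px = points_px, image = image, made_by = made_by,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "seed_annotation")
}

#' Read / write a seed annotation ROI as JSON
#'
#' @param path JSON file path.
#' @return [read_roi()] returns a `seed_annotation`; [write_roi()] returns
#'   `path` invisibly.
#' @export
read_roi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$points_px)) stop("ROI JSON missing field: points_px")
  seed_annotation(matrix(unlist(x$points_px), ncol = 2, byrow = FALSE),
                  image = x$image %||% "", made_by = x$made_by %||% "")
}

#' @rdname read_roi
#' @param roi a `seed_annotation`.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "seed_annotation"))
  jsonlite::write_json(
    list(image = roi$image, points_px = roi$points_px,
         made_by = roi$made_by, timestamp = roi$timestamp),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default tracing configuration
#'
#' All tunables of the tracing stage in one auditable place.
#'
#' @param snap_radius_um ridge-snapping search radius (um).
#' @param spacing_um centerline resampling step (um).
#' @param profile_step_um sampling step of the perpendicular intensity
#'   profile used for FWHM radius estimation (um).
#' @param max_radius_um largest radius the profile search considers (um).
#' @param n_fill_frames the filled-tubule working image is the
#'   maximum-intensity projection over this many final frames.
#' @param smooth_window centerline smoothing window (points) applied after
#'   snapping.
#' @return A named list of settings.
#' @export
trace_config <- function(snap_radius_um = 5, spacing_um = 1,
                         profile_step_um = 0.25, max_radius_um = 20,
                         n_fill_frames = 3, smooth_window = 7) {
  list(snap_radius_um = snap_radius_um, spacing_um = spacing_um,
       profile_step_um = profile_step_um, max_radius_um = max_radius_um,
       n_fill_frames = n_fill_frames, smooth_window = smooth_window)
}

#' Trace the proximal tubule from seed clicks
#'
#' Works on the maximum-intensity projection of the last few frames (the
#' completely filled tubule has the best contrast). Each point of the seed
#' polyline is snapped to the local intensity ridge: the perpendicular
#' intensity profile is measured, its full-width-at-half-maximum (FWHM)
#' interval above local background located, and the point moved to the
#' interval midpoint (shift capped at the search radius). The snapped
#' polyline is resampled at uniform arc-length spacing, re-snapped, lightly
#' smoothed, and the per-point radius estimated as half the FWHM.
#'
#' @param series an [image_series()] with a fully-filled late frame.
#' @param seeds a [seed_annotation()]; at least 2 points inside the image.
#' @param config a [trace_config()].
#' @return A `tubule_path`: data frame columns `s`, `x`, `y`, `r`,
#'   `r_reliable`; attributes `length_um`, `mean_diameter_um`, `volume_um3`
#'   (frusta sum), `volume_cylinder_um3` (single mean-diameter cylinder),
#'   `meets_length_criterion` (>= 45 um inclusion flag).
#' @export
trace_tubule <- function(series, seeds, config = trace_config()) {
  stopifnot(inherits(series, "image_series"),
            inherits(seeds, "seed_annotation"))
  d <- dim(series$frames)
  if (nrow(seeds$points_px) < 2) stop("need at least 2 seed points")
  if (any(seeds$points_px[, 1] < 0) || any(seeds$points_px[, 2] < 0) ||
      any(seeds$points_px[, 1] > d[2]) || any(seeds$points_px[, 2] > d[1]))
    stop("seed points outside image bounds")

  k_last <- max(1, d[3] - config$n_fill_frames + 1)
  img <- apply(series$frames[, , k_last:d[3], drop = FALSE], c(1, 2), max)
  px <- series$pixel_size
  pts <- (seeds$points_px + 0.5) * px  # physical um

  # Snap each point to the FWHM midpoint of its perpendicular profile.
  # Points whose profile halfwidth is an outlier (typically the junction
  # region, where an oblique profile clips the bright glomerulus) are not
  # trusted; their lateral shift is interpolated from accepted neighbours —
  # legitimate because a click-offset field is smooth along the path.
  snap_all <- function(P, cap) {
    n <- nrow(P)
    normal <- polyline_normals(P)
    mid <- rep(NA_real_, n); hw <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      prof <- perp_profile(img, P[i, ], normal[i, ], px, config)
      est <- fwhm_interval(prof$u, prof$v)
      if (est$bracketed) {
        mid[i] <- est$mid
        hw[i] <- est$halfwidth
      }
    }
    ok <- !is.na(hw)
    if (any(ok)) {
      med_hw <- median(hw[ok])
      ok <- ok & hw <= 1.4 * med_hw & abs(mid) <= cap
    }
    if (any(ok) && any(!ok)) {
      mid[!ok] <- approx(which(ok), mid[ok], xout = which(!ok), rule = 2)$y
    }
    apply_idx <- which(!is.na(mid))
    P[apply_idx, ] <- P[apply_idx, , drop = FALSE] +
      pmax(pmin(mid[apply_idx], cap), -cap) * normal[apply_idx, , drop = FALSE]
    P
  }
  pts <- snap_all(pts, config$snap_radius_um)
  rs <- resample_polyline(pts, config$spacing_um)
  P <- snap_all(rs$pts, config$snap_radius_um / 2)
  P <- smooth_polyline(P, config$smooth_window)
  rs <- resample_polyline(P, config$spacing_um)
  P <- rs$pts
  s <- rs$s

  check_self_intersection(P, s, config$spacing_um)

  # per-point FWHM radius
  n <- nrow(P)
  normal <- polyline_normals(P)
  r <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    prof <- perp_profile(img, P[i, ], normal[i, ], px, config)
    est <- fwhm_interval(prof$u, prof$v)
    r[i] <- est$halfwidth
    ok[i] <- est$bracketed
  }
  # halfwidth outliers (junction contamination) are unreliable too
  if (any(ok)) ok <- ok & r <= 1.4 * median(r[ok]) & r > 0
  if (!any(ok))
    stop(paste("radius estimation failed at every point (FWHM never",
               "bracketed); check contrast of the filled-tubule frame"))
  # unreliable radii fall back to the nearest reliable estimate
  if (any(!ok)) r[!ok] <- approx(which(ok), r[ok],
                                 xout = which(!ok), rule = 2)$y
  tubule_path(s = s, x = P[, 1], y = P[, 2], r = r, r_reliable = ok)
}

# Unit normals of a 2D polyline from central-difference tangents.
polyline_normals <- function(P) {
  n <- nrow(P)
  tang <- matrix(0, n, 2)
  tang[1, ] <- P[2, ] - P[1, ]
  tang[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- P[3:n, , drop = FALSE] -
      P[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  cbind(-tang[, 2], tang[, 1])
}

# Intensity profile perpendicular to the centerline at point P along unit
# normal; u spans +/- (max_radius + snap_radius).
perp_profile <- function(img, P, normal, px, config) {
  reach <- config$max_radius_um + config$snap_radius_um
  u <- seq(-reach, reach, by = config$profile_step_um)
  x <- P[1] + u * normal[1]
  y <- P[2] + u * normal[2]
  list(u = u, v = bilinear(img, x, y, px))
}

# FWHM of a single peak profile: background from the outer 20% of the tails,
# amplitude from the central region; half-max crossings located by linear
# interpolation on each side of the centre. Returns the interval midpoint
# (for snapping), half-width (radius), and whether both crossings exist.
fwhm_interval <- function(u, v) {
  n <- length(u)
  ntail <- max(3, floor(0.2 * n / 2))
  bg <- median(c(v[1:ntail], v[(n - ntail + 1):n]))
  centre <- which.min(abs(u))
  core <- v[abs(u) <= (max(u) / 3)]
  amp <- max(core) - bg
  out <- list(mid = NA_real_, halfwidth = NA_real_, bracketed = FALSE)
  if (amp <= 0) return(out)
  half <- bg + amp / 2
  above <- v >= half
  if (!above[centre]) {
    # centre may sit off-peak after a bad seed; use the widest above-half run
    runs <- rle(above)
    if (!any(runs$values)) return(out)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    w <- which(runs$values)
    pick <- w[which.max(runs$lengths[w])]
    centre <- floor((starts[pick] + ends[pick]) / 2)
  }
  il <- centre
  while (il > 1 && above[il - 1]) il <- il - 1
  ir <- centre
  while (ir < n && above[ir + 1]) ir <- ir + 1
  left <- if (il > 1)
    approx(v[c(il - 1, il)], u[c(il - 1, il)], xout = half)$y else NA_real_
  right <- if (ir < n)
    approx(v[c(ir + 1, ir)], u[c(ir + 1, ir)], xout = half)$y else NA_real_
  if (is.na(left) || is.na(right)) {
    out$halfwidth <- (u[ir] - u[il]) / 2
    return(out)
  }
  list(mid = (left + right) / 2, halfwidth = (right - left) / 2,
       bracketed = TRUE)
}

smooth_polyline <- function(P, window) {
  if (window < 3 || nrow(P) < window) return(P)
  k <- stats::filter(P, rep(1 / window, window), sides = 2)
  keep <- !is.na(k[, 1])
  P[keep, ] <- k[keep, ]
  P
}

check_self_intersection <- function(P, s, spacing = NULL) {
  n <- nrow(P)
  if (n < 4) return(invisible())
  # points far apart along the arc but nearly coincident in the plane
  # indicate a crossing; thresholds scale with the polyline's own spacing
  step <- median(diff(s))
  min_sep <- 3 * step
  d2 <- as.matrix(stats::dist(P))^2
  sep <- abs(outer(s, s, "-"))
  bad <- which(d2 < (0.75 * step)^2 & sep > min_sep, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "refined path self-intersects near arc positions %.1f and %.1f um",
      s[bad[1, 1]], s[bad[1, 2]]))
  }
  invisible()
}

#' Tubule path container
#'
#' @param s arc positions (um), uniform spacing.
#' @param x,y centerline coordinates (um).
#' @param r per-point radius (um).
#' @param r_reliable logical; FWHM bracketed at that point.
#' @return A `tubule_path` data frame with geometry attributes (see
#'   [trace_tubule()]).
#' @export
tubule_path <- function(s, x, y, r, r_reliable = rep(TRUE, length(s))) {
  df <- data.frame(s = s, x = x, y = y, r = r, r_reliable = r_reliable)
  if (any(r <= 0, na.rm = TRUE)) stop("all radii must be positive")
  len <- s[length(s)] - s[1]
  seg_len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (abs(len - seg_len) > 1e-6 * max(1, len) + 1e-4)
    len <- seg_len  # trust geometry over labels
  structure(df,
            class = c("tubule_path", "data.frame"),
            length_um = seg_len,
            mean_diameter_um = mean(2 * r),
            volume_um3 = frusta_volume(s, r),
            volume_cylinder_um3 = pi * mean(r)^2 * seg_len,
            meets_length_criterion = seg_len >= 45)
}

frusta_volume <- function(s, r) {
  n <- length(s)
  sum(pi * ((r[-n] + r[-1]) / 2)^2 * diff(s))
}

#' Tubule volume
#'
#' Frusta-of-cylinders sum over consecutive centerline points,
#' `sum(pi * ((r_i + r_{i+1}) / 2)^2 * ds_i)`, plus the simpler single
#' cylinder `pi * (mean_diameter / 2)^2 * length` for comparison.
#'
#' @param path a `tubule_path`.
#' @return list `volume_um3` (frusta), `volume_cylinder_um3`.
#' @export
tubule_volume <- function(path) {
  stopifnot(inherits(path, "tubule_path"))
  if (any(path$r <= 0)) stop("all radii must be positive")
  list(volume_um3 = frusta_volume(path$s, path$r),
       volume_cylinder_um3 = pi * (attr(path, "mean_diameter_um") / 2)^2 *
         attr(path, "length_um"))
}

#' @export
print.tubule_path <- function(x, ...) {
  cat(sprintf(
    paste0("<tubule_path> %d points, length %.1f um, mean diameter %.2f um,",
           " volume %.0f um^3%s\n"),
    nrow(x), attr(x, "length_um"), attr(x, "mean_diameter_um"),
    attr(x, "volume_um3"),
    if (attr(x, "meets_length_criterion")) "" else " [below 45 um minimum]"))
  invisible(x)
}

#' Export a tubule path
#'
#' CSV of `(s, x, y, r)` plus a JSON summary of the scalar geometry.
#'
#' @param path a `tubule_path`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the summary list.
#' @export
export_tubule_path <- function(path, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(path, "tubule_path"))
  if (!is.null(csv_path))
    write.csv(path[, c("s", "x", "y", "r")], csv_path, row.names = FALSE)
  summary <- list(length_um = attr(path, "length_um"),
                  mean_diameter_um = attr(path, "mean_diameter_um"),
                  volume_um3 = attr(path, "volume_um3"),
                  volume_cylinder_um3 = attr(path, "volume_cylinder_um3"),
                  meets_length_criterion = attr(path, "meets_length_criterion"),
                  n_points = nrow(path))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
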