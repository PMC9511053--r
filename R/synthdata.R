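# Synthetic multiphoton phantoms with analytic ground truth.
#
# The generator emulates the two acquisitions the analysis consumes:
#  (a) a freely filtered tracer bolus (Lucifer-Yellow analogue) filling a
#      proximal tubule downstream of a glomerulus, imaged as a single-plane
#      time series at 6 frames/s;
#  (b) curved/straight vessels and a spherical capillary tuft embedded in a
#      noisy 3D volume, imaged as a z-stack (default 1 um z-step, 120 um).
#
# All geometry is in physical micrometres. Rasterization samples pixel
# centres: 0-based index i maps to physical (i + 0.5) * pixel_size.

#' Nephron filling phantom
#'
#' Describes a glomerulus plus proximal tubule with a known true snGFR.
#' The tracer front advances with local velocity `v(s) = Q / A(s)` where `Q`
#' is the true snGFR converted to um^3/s and `A(s) = pi r(s)^2`, so the
#' ground-truth arrival time at arc length `s` is
#' `t0 + integral_0^s A(u) du / Q`.
#'
#' Defaults describe a realistic superficial nephron at this acquisition:
#' a 200 um visible proximal tubule segment (comfortably above the 45 um
#' inclusion minimum) of 10 um luminal radius, 1 um/px sampling, 6 frames/s,
#' photon-counting noise with Poisson gain 1 and read noise SD 3 on a
#' background of 20 photons with tracer plateau 150 photons.
#'
#' @param true_sngfr true single-nephron GFR, nl/min. Must be positive.
#' @param tubule_length visible proximal tubule arc length, um. Lengths below
#'   45 um are permitted (for negative tests of the inclusion criterion) but
#'   warn.
#' @param tubule_radius luminal radius, um; a scalar or a per-point profile
#'   (linearly interpolated along the tubule).
#' @param centerline optional user-supplied centerline (n x 2 matrix, um);
#'   overrides `tubule_length`.
#' @param glomerulus_radius radius of the glomerular disc, um.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames (default 1/6).
#' @param n_frames number of frames.
#' @param bolus_time time at which the tracer reaches the glomerulus, s.
#' @param rise_width 10--90\% rise time of the logistic intensity ramp at a
#'   fixed position, s. A dispersed (not step) front keeps sub-frame
#'   interpolation meaningful.
#' @param background_level mean background, photons.
#' @param peak_intensity tracer plateau above background, photons.
#' @param poisson_gain detector gain applied inside the Poisson stage.
#' @param gaussian_read_sd additive Gaussian read noise SD, photons.
#' @param noise logical; disable for exact deterministic frames.
#' @param seed integer RNG seed; the generator never perturbs the caller's
#'   RNG state.
#' @return An object of class `nephron_phantom`.
#' @export
nephron_phantom <- function(true_sngfr = 4.24,
                            tubule_length = 200,
                            tubule_radius = 10,
                            centerline = NULL,
                            glomerulus_radius = 35,
                            pixel_size = 1.0,
                            frame_interval = 1 / 6,
                            n_frames = 80,
                            bolus_time = 1.0,
                            rise_width = 0.15,
                            background_level = 20,
                            peak_intensity = 150,
                            poisson_gain = 1,
                            gaussian_read_sd = 3,
                            noise = TRUE,
                            seed = 1L) {
  stop_if_not_scalar_pos(true_sngfr, "true_sngfr")
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  if (any(tubule_radius <= 0)) stop("all radii must be > 0")
  glom_center <- c(15 + glomerulus_radius, 60)
  if (is.null(centerline)) {
    stop_if_not_scalar_pos(tubule_length, "tubule_length")
    centerline <- curved_centerline(
      start = glom_center + c(glomerulus_radius, 0),
      length = tubule_length)
  } else {
    centerline <- as.matrix(centerline)
  }
  len <- max(arc_lengths(centerline))
  if (len < 45)
    warning(sprintf(
      "tubule arc length %.1f um is below the 45 um inclusion minimum", len))
  structure(list(
    centerline = centerline, tubule_radius = tubule_radius,
    glomerulus_center = glom_center, glomerulus_radius = glomerulus_radius,
    true_sngfr = true_sngfr, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    bolus_time = bolus_time, rise_width = rise_width,
    background_level = background_level, peak_intensity = peak_intensity,
    poisson_gain = poisson_gain, gaussian_read_sd = gaussian_read_sd,
    noise = isTRUE(noise), seed = as.integer(seed)),
    class = "nephron_phantom")
}

# Gentle sinusoidally curving path of exact arc length, built by integrating
# a heading angle; emulates the meandering of a superficial PT segment.
curved_centerline <- function(start, length, amplitude = 0.35,
                              period = 90, ds = 0.5) {
  s <- seq(0, length, by = ds)
  if (s[length(s)] < length) s <- c(s, length)
  theta <- amplitude * sin(2 * pi * s / period)
  # mid-point rule on headings keeps per-step length exactly ds
  dstep <- diff(s)
  th_mid <- (theta[-1] + theta[-length(theta)]) / 2
  x <- start[1] + c(0, cumsum(dstep * cos(th_mid)))
  y <- start[2] + c(0, cumsum(dstep * sin(th_mid)))
  cbind(x, y)
}

# logistic scale parameter from a 10-90% rise time
logistic_scale <- function(rise_width) rise_width / (2 * log(9))

nl_min_to_um3_s <- function(q_nl_min) q_nl_min * 1e6 / 60

#' Generate a tracer-filling time series from a nephron phantom
#'
#' Renders the advancing tracer front: every pixel inside the tubule lumen
#' turns on with a logistic ramp centred on the ground-truth front arrival
#' time at its arc position; the glomerular disc fills at the bolus time.
#' Photon noise is Poisson(signal x gain)/gain plus Gaussian read noise.
#'
#' @param phantom a [nephron_phantom()].
#' @return A list with elements `series` (an [image_series()]) and `truth`,
#'   a `ground_truth` list holding per-position front arrival times
#'   (`arrival`: data frame `s`, `t`), the exact tubule volume (`volume_um3`),
#'   total fill time, per-position front velocity, the rasterized tubule and
#'   glomerulus masks, and a `truncated` flag set when the acquisition ends
#'   before the front reaches the tubule end (mirroring real truncated
#'   acquisitions; not an error).
#' @export
generate_filling_series <- function(phantom) {
  p <- phantom
  stopifnot(inherits(p, "nephron_phantom"))
  fine <- resample_polyline(p$centerline, spacing = 0.25,
                            scalars = list(r = radius_profile(p)))
  s <- fine$s
  r <- fine$scalars$r
  A <- pi * r^2
  Q <- nl_min_to_um3_s(p$true_sngfr)
  arrival <- p$bolus_time + cumtrapz(s, A) / Q
  volume <- trapz(s, A)

  # canvas sized from geometry with a margin
  rmax <- max(r)
  all_x <- c(fine$pts[, 1], p$glomerulus_center[1])
  all_y <- c(fine$pts[, 2], p$glomerulus_center[2])
  pad <- max(rmax, p$glomerulus_radius) + 10
  nx <- ceiling((max(all_x) + pad) / p$pixel_size)
  ny <- ceiling((max(all_y) + pad) / p$pixel_size)

  px <- (seq_len(nx) - 0.5) * p$pixel_size
  py <- (seq_len(ny) - 0.5) * p$pixel_size

  # tubule mask: nearest fine centerline point within local radius.
  bb <- c(range(fine$pts[, 1]) + c(-1, 1) * (rmax + 2),
          range(fine$pts[, 2]) + c(-1, 1) * (rmax + 2))
  jj <- which(px >= bb[1] & px <= bb[2])
  ii <- which(py >= bb[3] & py <= bb[4])
  cand <- expand.grid(i = ii, j = jj)
  cx <- px[cand$j]; cy <- py[cand$i]
  best_d2 <- rep(Inf, nrow(cand)); best_k <- rep(1L, nrow(cand))
  chunk <- 150L
  for (k0 in seq(1L, length(s), by = chunk)) {
    ks <- k0:min(k0 + chunk - 1L, length(s))
    d2 <- outer(cx, fine$pts[ks, 1], "-")^2 +
          outer(cy, fine$pts[ks, 2], "-")^2
    mk <- max.col(-d2, ties.method = "first")
    mv <- d2[cbind(seq_len(nrow(d2)), mk)]
    upd <- mv < best_d2
    best_d2[upd] <- mv[upd]
    best_k[upd] <- ks[mk[upd]]
  }
  in_tub <- best_d2 <= r[best_k]^2
  tub_idx <- (cand$j[in_tub] - 1L) * ny + cand$i[in_tub]
  tub_arr <- arrival[best_k[in_tub]]

  # glomerular disc fills at the bolus time
  gd2 <- outer((py - p$glomerulus_center[2])^2,
               (px - p$glomerulus_center[1])^2, "+")
  glom_idx <- which(gd2 <= p$glomerulus_radius^2)

  sig_idx <- c(tub_idx, glom_idx)
  sig_arr <- c(tub_arr, rep(p$bolus_time, length(glom_idx)))
  dup <- duplicated(sig_idx)
  sig_idx <- sig_idx[!dup]; sig_arr <- sig_arr[!dup]

  s0 <- logistic_scale(p$rise_width)
  tk <- (seq_len(p$n_frames) - 1) * p$frame_interval
  frames <- array(p$background_level, dim = c(ny, nx, p$n_frames))
  npx <- as.integer(ny) * nx
  # integrating detector: frame k accumulates over an exposure of one frame
  # interval centred on its timestamp, so the stored value is the mean of
  # the logistic ramp over [t_k - dt/2, t_k + dt/2] (closed form via the
  # softplus antiderivative)
  half <- p$frame_interval / 2
  for (k in seq_len(p$n_frames)) {
    mean_ramp <- s0 / p$frame_interval *
      (softplus((tk[k] + half - sig_arr) / s0) -
       softplus((tk[k] - half - sig_arr) / s0))
    frames[sig_idx + (k - 1L) * npx] <- p$background_level +
      p$peak_intensity * mean_ramp
  }
  if (p$noise) {
    frames <- with_seed(p$seed, {
      n <- length(frames)
      counts <- rpois(n, lambda = frames * p$poisson_gain) / p$poisson_gain
      counts + rnorm(n, sd = p$gaussian_read_sd)
    })
    dim(frames) <- c(ny, nx, p$n_frames)
  }

  tub_mask <- matrix(FALSE, ny, nx); tub_mask[tub_idx] <- TRUE
  glom_mask <- matrix(FALSE, ny, nx); glom_mask[glom_idx] <- TRUE
  truth <- structure(list(
    arrival = data.frame(s = s, t = arrival),
    volume_um3 = volume,
    fill_time_s = arrival[length(arrival)] - p$bolus_time,
    velocity_um_s = Q / A,
    flow_um3_s = Q,
    true_sngfr = p$true_sngfr,
    centerline_fine = fine$pts,
    radius_fine = r,
    tubule_mask = tub_mask,
    glomerulus_mask = glom_mask,
    truncated = arrival[length(arrival)] > tk[length(tk)]),
    class = "ground_truth")
  list(series = image_series(frames, p$pixel_size, p$frame_interval),
       truth = truth)
}

radius_profile <- function(phantom) {
  n <- nrow(phantom$centerline)
  r <- phantom$tubule_radius
  if (length(r) == 1) rep(r, n)
  else approx(seq(0, 1, length.out = length(r)), r,
              xout = seq(0, 1, length.out = n))$y
}

#' Seed annotation from phantom ground truth
#'
#' Emulates the manual clicks a user would place along the tubule from the
#' glomerulotubular junction outward (the click order defines the flow
#' direction). Offsets and jitter support robustness tests.
#'
#' @param truth `truth` element from [generate_filling_series()].
#' @param phantom the phantom that produced it.
#' @param n_seeds number of clicks.
#' @param offset_um systematic perpendicular offset of every click, um.
#' @param jitter_um SD of isotropic Gaussian click jitter, um.
#' @param seed RNG seed for the jitter.
#' @return A `seed_annotation` (see [read_roi()]).
#' @export
phantom_seeds <- function(truth, phantom, n_seeds = 8, offset_um = 0,
                          jitter_um = 0, seed = 1L) {
  pts <- truth$centerline_fine
  s <- arc_lengths(pts)
  picks <- approx(s, seq_along(s), xout = seq(0, max(s),
                                              length.out = n_seeds))$y
  pick <- unique(round(picks))
  P <- pts[pick, , drop = FALSE]
  if (offset_um != 0) {
    tang <- rbind(P[2, ] - P[1, ],
                  P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    P <- P + offset_um * cbind(-tang[, 2], tang[, 1])
  }
  if (jitter_um > 0) {
    P <- P + with_seed(seed, matrix(rnorm(length(P), sd = jitter_um),
                                    ncol = 2))
  }
  seed_annotation(points_px = P / phantom$pixel_size - 0.5,
                  image = "<phantom>", made_by = "phantom_seeds")
}

# ---- 3D vessel phantoms ----

#' Vessel / glomerular tuft phantom
#'
#' A tube of known diameter (constant or per-point) along a 3D centerline,
#' optionally with a sphere standing in for the glomerular capillary tuft,
#' rendered into a noisy z-stack. Defaults: 1 um z-step over 120 um depth,
#' 0.5 um in-plane pixels.
#'
#' @param diameter tube diameter, um; scalar or per-point. Must exceed twice
#'   the in-plane voxel size to be resolvable.
#' @param centerline n x 3 matrix (um) or `NULL` for a straight z-aligned
#'   tube through the stack centre.
#' @param voxel_size `(dx, dy, dz)` um; z default 1 um.
#' @param depth stack depth, um; must be an integer multiple of the z-step.
#' @param sphere_center,sphere_radius optional tuft sphere (um).
#' @param margin_um in-plane margin around the geometry, um.
#' @param background_level,peak_intensity,poisson_gain,gaussian_read_sd,noise,seed
#'   noise model as in [nephron_phantom()].
#' @return An object of class `vessel_phantom`.
#' @export
vessel_phantom <- function(diameter = 12,
                           centerline = NULL,
                           voxel_size = c(0.5, 0.5, 1),
                           depth = 120,
                           sphere_center = NULL,
                           sphere_radius = NULL,
                           margin_um = 5,
                           background_level = 20,
                           peak_intensity = 150,
                           poisson_gain = 1,
                           gaussian_read_sd = 3,
                           noise = TRUE,
                           seed = 1L) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers")
  nz <- depth / voxel_size[3]
  if (abs(nz - round(nz)) > 1e-9)
    stop("stack depth must be an integer multiple of the z-step")
  if (any(diameter <= 2 * max(voxel_size[1:2])))
    stop(sprintf(
      "diameter must exceed 2 x in-plane voxel size (%g um) to be resolvable",
      2 * max(voxel_size[1:2])))
  rmax <- max(diameter) / 2
  if (is.null(centerline)) {
    half <- rmax + margin_um
    centerline <- cbind(half, half, seq(0.5 * voxel_size[3],
                                        depth - 0.5 * voxel_size[3],
                                        length.out = 64))
  }
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3) stop("'centerline' must be n x 3 (um)")
  structure(list(
    centerline = centerline, diameter = diameter, voxel_size = voxel_size,
    depth = depth, sphere_center = sphere_center,
    sphere_radius = sphere_radius, margin_um = margin_um,
    background_level = background_level, peak_intensity = peak_intensity,
    poisson_gain = poisson_gain, gaussian_read_sd = gaussian_read_sd,
    noise = isTRUE(noise), seed = as.integer(seed)),
    class = "vessel_phantom")
}

#' Generate a z-stack from a vessel phantom
#'
#' Voxelizes the tube (and optional tuft sphere) by voxel-centre inclusion,
#' adds foreground intensity over background, and applies photon noise.
#' A tube extending outside the stack is an error naming the out-of-bounds
#' extent (a real acquisition would be re-positioned).
#'
#' @param phantom a [vessel_phantom()].
#' @return list(stack = [vessel_stack()], truth = ground truth with analytic
#'   `mask`, `diameter`, `centerline`, tube length, and `sphere_volume_um3`).
#' @export
generate_vessel_stack <- function(phantom) {
  p <- phantom
  stopifnot(inherits(p, "vessel_phantom"))
  vs <- p$voxel_size
  nz <- as.integer(round(p$depth / vs[3]))
  fine <- resample_polyline(p$centerline, spacing = min(vs) / 2)
  # per-point radii (scalar or profile), interpolated on the fine centerline
  rr <- if (length(p$diameter) == 1) {
    rep(p$diameter / 2, length(fine$s))
  } else {
    approx(seq(0, 1, length.out = length(p$diameter)), p$diameter / 2,
           xout = fine$s / max(fine$s))$y
  }

  # the tube surface may be clipped by the stack faces (a vessel crossing
  # the imaged volume is the normal case); only a centerline leaving the
  # volume is an error
  if (min(fine$pts[, 3]) < 0 || max(fine$pts[, 3]) > p$depth ||
      min(fine$pts[, 1:2]) < 0)
    stop(sprintf(
      "tube not fully inside stack: centerline z extent [%.2f, %.2f] um vs [0, %g] um",
      min(fine$pts[, 3]), max(fine$pts[, 3]), p$depth))

  pad <- max(rr, p$sphere_radius %||% 0) + p$margin_um
  xs <- c(fine$pts[, 1], p$sphere_center[1])
  ys <- c(fine$pts[, 2], p$sphere_center[2])
  nx <- ceiling((max(xs) + pad) / vs[1])
  ny <- ceiling((max(ys) + pad) / vs[2])
  px <- (seq_len(nx) - 0.5) * vs[1]
  py <- (seq_len(ny) - 0.5) * vs[2]
  pz <- (seq_len(nz) - 0.5) * vs[3]

  mask <- array(FALSE, dim = c(ny, nx, nz))
  # tube: chunk over fine centerline points, mark voxels within local radius
  bb <- list(x = range(fine$pts[, 1]) + c(-1, 1) * (max(rr) + 1),
             y = range(fine$pts[, 2]) + c(-1, 1) * (max(rr) + 1),
             z = range(fine$pts[, 3]) + c(-1, 1) * (max(rr) + 1))
  ix <- which(px >= bb$x[1] & px <= bb$x[2])
  iy <- which(py >= bb$y[1] & py <= bb$y[2])
  iz <- which(pz >= bb$z[1] & pz <= bb$z[2])
  if (length(ix) && length(iy) && length(iz)) {
    grd <- expand.grid(i = iy, j = ix, k = iz)
    gx <- px[grd$j]; gy <- py[grd$i]; gz <- pz[grd$k]
    best <- rep(Inf, nrow(grd)); bestk <- rep(1L, nrow(grd))
    chunk <- 60L
    for (k0 in seq(1L, length(fine$s), by = chunk)) {
      ks <- k0:min(k0 + chunk - 1L, length(fine$s))
      d2 <- outer(gx, fine$pts[ks, 1], "-")^2 +
            outer(gy, fine$pts[ks, 2], "-")^2 +
            outer(gz, fine$pts[ks, 3], "-")^2
      mk <- max.col(-d2, ties.method = "first")
      mv <- d2[cbind(seq_len(nrow(d2)), mk)]
      upd <- mv < best
      best[upd] <- mv[upd]; bestk[upd] <- ks[mk[upd]]
    }
    inside <- best <= rr[bestk]^2
    mask[cbind(grd$i, grd$j, grd$k)[inside, , drop = FALSE]] <- TRUE
  }
  sphere_volume <- NULL
  if (!is.null(p$sphere_center)) {
    sc <- p$sphere_center; sr <- p$sphere_radius
    d2 <- outer(outer((py - sc[2])^2, (px - sc[1])^2, "+"),
                (pz - sc[3])^2, "+")
    mask[d2 <= sr^2] <- TRUE
    sphere_volume <- 4 / 3 * pi * sr^3
  }

  vox <- array(p$background_level, dim = dim(mask))
  vox[mask] <- p$background_level + p$peak_intensity
  if (p$noise) {
    vox <- with_seed(p$seed, {
      n <- length(vox)
      rpois(n, vox * p$poisson_gain) / p$poisson_gain +
        rnorm(n, sd = p$gaussian_read_sd)
    })
    dim(vox) <- dim(mask)
  }

  truth <- structure(list(
    mask = mask,
    centerline = fine$pts,
    diameter = 2 * rr,
    tube_length_um = max(fine$s),
    sphere_center = p$sphere_center,
    sphere_volume_um3 = sphere_volume),
    class = "ground_truth")
  list(stack = vessel_stack(vox, vs), truth = truth)
}
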