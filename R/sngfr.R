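# Single-nephron GFR from tracer-front kinetics along the traced tubule.
#
# The tracer front reaches arc position s when the filtrate has displaced
# the luminal volume V(s) upstream of s, so t_arr(s) = t0 + V(s) / Q. The
# flow Q (um^3/s) is the slope of V(s) against arrival time; snGFR in
# nl/min is Q * 60 / 1e6 (1 nl/min fills 1e6 um^3 in 60 s).

#' Default snGFR analysis configuration
#'
#' @param position_spacing_um arc spacing of measurement positions (um).
#' @param n_baseline_frames pre-bolus frames used for baseline subtraction.
#' @param plateau_frames frames from the end of the series whose median
#'   defines the per-position plateau.
#' @param noise_floor_sd plateau must exceed this multiple of the baseline
#'   SD to count as signal.
#' @param min_valid_fraction minimum fraction of positions with a detected
#'   arrival for [compute_sngfr()] to proceed.
#' @return Named list of settings.
#' @export
sngfr_config <- function(position_spacing_um = 2, n_baseline_frames = 5,
                         plateau_frames = 10, noise_floor_sd = 3,
                         min_valid_fraction = 0.6) {
  list(position_spacing_um = position_spacing_um,
       n_baseline_frames = n_baseline_frames,
       plateau_frames = plateau_frames,
       noise_floor_sd = noise_floor_sd,
       min_valid_fraction = min_valid_fraction)
}

#' Extract per-position intensity traces
#'
#' For each arc position along the tubule (default every 2 um), mean
#' intensity over a disc of the local radius centred on the centerline, per
#' frame; the mean of the first pre-bolus frames is subtracted per position.
#' Tracer already present at t = 0 (no clean baseline) is an error: such an
#' acquisition cannot be analysed and must be re-acquired.
#'
#' @param series an [image_series()].
#' @param path a `tubule_path` lying inside the field of view.
#' @param config an [sngfr_config()].
#' @return An `intensity_trace`: list with `s` (positions), `t` (frame
#'   times), `I` (positions x frames matrix, baseline-subtracted),
#'   `baseline_sd` per position.
#' @export
extract_traces <- function(series, path, config = sngfr_config()) {
  stopifnot(inherits(series, "image_series"),
            inherits(path, "tubule_path"))
  d <- dim(series$frames)
  px <- series$pixel_size
  s_out <- seq(min(path$s), max(path$s), by = config$position_spacing_um)
  cx <- approx(path$s, path$x, xout = s_out)$y
  cy <- approx(path$s, path$y, xout = s_out)$y
  cr <- approx(path$s, path$r, xout = s_out)$y
  if (any(cx < 0 | cy < 0 | cx > d[2] * px | cy > d[1] * px))
    stop("tubule path extends outside the field of view")

  npx <- d[1] * d[2]
  pix <- lapply(seq_along(s_out), function(i) {
    jr <- max(1, floor((cx[i] - cr[i]) / px)):min(d[2],
                                                  ceiling((cx[i] + cr[i]) / px))
    ir <- max(1, floor((cy[i] - cr[i]) / px)):min(d[1],
                                                  ceiling((cy[i] + cr[i]) / px))
    g <- expand.grid(i = ir, j = jr)
    d2 <- ((g$j - 0.5) * px - cx[i])^2 + ((g$i - 0.5) * px - cy[i])^2
    inside <- d2 <= cr[i]^2
    if (!any(inside)) inside <- d2 == min(d2)  # tiny radius: nearest pixel
    (g$j[inside] - 1L) * d[1] + g$i[inside]
  })

  flat <- matrix(series$frames, nrow = npx)
  I <- t(vapply(pix, function(idx) colMeans(flat[idx, , drop = FALSE]),
                numeric(d[3])))
  k <- config$n_baseline_frames
  if (k < 1 || k >= d[3]) stop("invalid baseline window")
  base_mean <- rowMeans(I[, 1:k, drop = FALSE])
  base_sd <- apply(I[, 1:k, drop = FALSE], 1, sd)
  plateau <- apply(I[, (d[3] - config$plateau_frames + 1):d[3],
                     drop = FALSE], 1, median)
  # Tracer already present at t = 0 (no clean pre-bolus baseline): the
  # first-frame signal above the *image* background (estimated from the
  # frame border, which never contains the tubule) is compared to the
  # plateau level above background.
  border <- c(series$frames[1, , 1], series$frames[d[1], , 1],
              series$frames[, 1, 1], series$frames[, d[2], 1])
  bg0 <- median(border)
  lifted <- (plateau - bg0) > 0 &
    (I[, 1] - bg0) > 0.5 * (plateau - bg0)
  if (mean(lifted) > 0.5)
    stop(paste("tracer already present at t = 0 (no pre-bolus baseline);",
               "re-acquire or regenerate with a later bolus"))
  I <- I - base_mean
  t <- (seq_len(d[3]) - 1) * series$frame_interval
  structure(list(s = s_out, t = t, I = I, baseline_sd = base_sd,
                 frame_interval = series$frame_interval),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d positions x %d frames (dt = %.4g s)\n",
              length(x$s), length(x$t), x$frame_interval))
  invisible(x)
}

#' Front arrival time at one position
#'
#' First crossing of 50\% of the position's plateau amplitude (plateau =
#' median of the last frames), with sub-frame linear interpolation between
#' the bracketing frames. Returns `NA` with a `no_signal` flag when the
#' plateau does not exceed the noise floor; when the intensity crosses the
#' threshold more than once, the earliest crossing is used and
#' `multiple_crossings` flagged.
#'
#' @param trace an `intensity_trace`.
#' @param position index into `trace$s`.
#' @param config an [sngfr_config()].
#' @return list `t_arrival` (s, `NA` if undetectable), `flags` (character).
#' @export
front_arrival <- function(trace, position, config = sngfr_config()) {
  stopifnot(inherits(trace, "intensity_trace"))
  v <- trace$I[position, ]
  t <- trace$t
  nlast <- min(config$plateau_frames, length(v))
  plateau <- median(v[(length(v) - nlast + 1):length(v)])
  floor_level <- config$noise_floor_sd * max(trace$baseline_sd[position],
                                             .Machine$double.eps)
  if (!is.finite(plateau) || plateau <= floor_level)
    return(list(t_arrival = NA_real_, flags = "no_signal"))
  th <- 0.5 * plateau
  above <- v >= th
  cross <- which(!above[-length(v)] & above[-1])
  if (length(cross) == 0) {
    if (above[1]) return(list(t_arrival = t[1], flags = "already_above"))
    return(list(t_arrival = NA_real_, flags = "no_crossing"))
  }
  flags <- character(0)
  if (length(cross) > 1) flags <- "multiple_crossings"
  i <- cross[1]
  t_hat <- t[i] + (th - v[i]) / (v[i + 1] - v[i]) *
    (t[i + 1] - t[i])
  list(t_arrival = t_hat, flags = flags)
}

#' Compute snGFR from arrival times
#'
#' Primary "volumetric regression" estimator: least-squares regression of
#' cumulative luminal volume `V(s)` on arrival time `t_arr(s)`; the slope is
#' the flow Q in um^3/s and `snGFR = Q * 60 / 1e6` nl/min. The literal
#' "volume change over time" two-point estimator (endpoint volume over
#' endpoint transit time) is reported alongside for comparison.
#'
#' @param path a `tubule_path`.
#' @param arrivals numeric vector of arrival times at arc positions
#'   `attr(arrivals, "s")` (as produced by [measure_sngfr()]), or a data
#'   frame with columns `s`, `t`.
#' @param config an [sngfr_config()].
#' @return An `sngfr_result`: list with `sngfr_nl_min`, `sngfr_two_point`,
#'   `flow_um3_s`, `r_squared`, `transit_s_per_um`, `total_transit_s`,
#'   `volume_um3`, `valid_fraction`, `flags`.
#' @export
compute_sngfr <- function(path, arrivals, config = sngfr_config()) {
  stopifnot(inherits(path, "tubule_path"))
  if (is.data.frame(arrivals)) {
    s <- arrivals$s; t_arr <- arrivals$t
  } else {
    s <- attr(arrivals, "s"); t_arr <- as.numeric(arrivals)
  }
  if (is.null(s) || length(s) != length(t_arr))
    stop("arrivals must carry arc positions of equal length")
  valid <- is.finite(t_arr)
  valid_fraction <- mean(valid)
  if (sum(valid) < 3) stop("fewer than 3 valid arrival positions")
  if (valid_fraction < config$min_valid_fraction)
    stop(sprintf(
      "only %.0f%% of positions have detected arrivals (< %.0f%% required)",
      100 * valid_fraction, 100 * config$min_valid_fraction))

  flags <- character(0)
  if (any(diff(t_arr[valid]) < 0)) flags <- c(flags, "nonmonotone_arrivals")

  # cumulative luminal volume from the junction to each position
  Vs <- cumtrapz(path$s, pi * path$r^2)
  V <- approx(path$s, Vs, xout = s)$y
  fit <- lm(V[valid] ~ t_arr[valid])
  Q <- unname(coef(fit)[2])
  if (!is.finite(Q) || Q <= 0)
    stop("retrograde or undetectable flow (non-positive volume-time slope)")
  ss_tot <- sum((V[valid] - mean(V[valid]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  i1 <- which(valid)[1]; i2 <- rev(which(valid))[1]
  dt <- t_arr[i2] - t_arr[i1]
  two_point <- if (dt > 0) (V[i2] - V[i1]) / dt else NA_real_
  structure(list(
    sngfr_nl_min = Q * 60 / 1e6,
    sngfr_two_point = if (is.na(two_point)) NA_real_ else two_point * 60 / 1e6,
    flow_um3_s = Q,
    r_squared = r2,
    transit_s_per_um = dt / (s[i2] - s[i1]),
    total_transit_s = dt,
    volume_um3 = attr(path, "volume_um3"),
    valid_fraction = valid_fraction,
    arrivals = data.frame(s = s, t = t_arr, V = V),
    flags = flags),
    class = "sngfr_result")
}

#' @export
print.sngfr_result <- function(x, ...) {
  cat(sprintf(
    paste0("<sngfr_result> snGFR = %.3f nl/min (two-point %.3f), R^2 = %.4f,",
           " %d%% positions valid%s\n"),
    x$sngfr_nl_min, x$sngfr_two_point, x$r_squared,
    round(100 * x$valid_fraction),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' One-call snGFR measurement
#'
#' Chains [extract_traces()], [front_arrival()] at every position, and
#' [compute_sngfr()].
#'
#' @param series an [image_series()].
#' @param path a `tubule_path` (from [trace_tubule()]).
#' @param config an [sngfr_config()].
#' @return An `sngfr_result`.
#' @export
measure_sngfr <- function(series, path, config = sngfr_config()) {
  trace <- extract_traces(series, path, config)
  arr <- vapply(seq_along(trace$s),
                function(i) front_arrival(trace, i, config)$t_arrival,
                numeric(1))
  attr(arr, "s") <- trace$s
  compute_sngfr(path, arr, config)
}
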