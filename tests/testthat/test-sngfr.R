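# Front arrival and flow estimation against the generator's analytic
# ground truth and closed-form unit conversions.

# hand-built intensity trace: one position, step from 0 to plateau
make_trace <- function(v, fi = 1 / 6, baseline_sd = 0.01) {
  structure(list(s = 0, t = (seq_along(v) - 1) * fi,
                 I = matrix(v, nrow = 1), baseline_sd = baseline_sd,
                 frame_interval = fi),
            class = "intensity_trace")
}

test_that("arrival interpolates to the half-rise between bracketing frames", {
  # intensity 0 up to frame index 10 (0-based), plateau P from frame 11
  fi <- 1 / 6
  v <- c(rep(0, 11), rep(8, 20))
  res <- front_arrival(make_trace(v, fi))
  expect_equal(res$t_arrival, 10.5 * fi, tolerance = 1e-12)
})

test_that("an all-zero trace yields a flagged missing arrival", {
  res <- front_arrival(make_trace(rep(0, 30)))
  expect_true(is.na(res$t_arrival))
  expect_identical(res$flags, "no_signal")
})

test_that("multiple threshold crossings use the earliest and are flagged", {
  v <- c(rep(0, 5), 6, 0, rep(8, 20))  # spike, dip, then the real front
  res <- front_arrival(make_trace(v))
  expect_identical(res$flags, "multiple_crossings")
  expect_lt(res$t_arrival, 1)
})

test_that("noise-free traces are zero before arrival and deterministic", {
  gen <- nf_nephron(4)
  path <- trace_tubule(gen$series, phantom_seeds(gen$truth, gen$phantom))
  tr1 <- extract_traces(gen$series, path)
  tr2 <- extract_traces(gen$series, path)
  expect_identical(tr1$I, tr2$I)
  for (i in c(5, 40, 90)) {
    t_true <- approx(gen$truth$arrival$s, gen$truth$arrival$t,
                     xout = tr1$s[i])$y
    # a margin of a few ramp widths: the logistic front has smooth tails
    pre <- tr1$t < t_true - 0.4
    expect_lt(max(abs(tr1$I[i, pre])), 1e-3 * gen$phantom$peak_intensity)
    expect_gt(max(tr1$I[i, ]), 0.8 * gen$phantom$peak_intensity)
  }
})

test_that("arrival at 6 fps is within half a frame of ground truth", {
  gen <- nf_nephron(4)
  path <- trace_tubule(gen$series, phantom_seeds(gen$truth, gen$phantom))
  tr <- extract_traces(gen$series, path)
  arr <- vapply(seq_along(tr$s),
                function(i) front_arrival(tr, i)$t_arrival, numeric(1))
  t_true <- approx(gen$truth$arrival$s, gen$truth$arrival$t, xout = tr$s)$y
  expect_lt(max(abs(arr - t_true), na.rm = TRUE), 1 / 12)
})

test_that("a misestimated averaging disc attenuates amplitude, not timing", {
  gen <- nf_nephron(4)
  path <- trace_tubule(gen$series, phantom_seeds(gen$truth, gen$phantom))
  tr_ok <- extract_traces(gen$series, path)
  path_big <- path
  path_big$r <- path$r * 3
  tr_big <- extract_traces(gen$series, path_big)
  amp_ok <- apply(tr_ok$I, 1, max)
  amp_big <- apply(tr_big$I, 1, max)
  expect_lt(median(amp_big / amp_ok), 0.5)
  a_ok <- vapply(seq_along(tr_ok$s),
                 function(i) front_arrival(tr_ok, i)$t_arrival, numeric(1))
  a_big <- vapply(seq_along(tr_big$s),
                  function(i) front_arrival(tr_big, i)$t_arrival, numeric(1))
  expect_lt(median(abs(a_big - a_ok), na.rm = TRUE), 0.1)
})

test_that("exactly linear V(t) at 1e6/60 um^3/s gives snGFR 1.0 and R^2 1", {
  s <- seq(0, 100, by = 2)
  p <- tubule_path(s = s, x = s, y = rep(0, length(s)),
                   r = rep(10, length(s)))
  V <- cumsum(c(0, diff(s))) * pi * 100
  arrivals <- data.frame(s = s, t = V / (1e6 / 60))
  res <- compute_sngfr(p, arrivals)
  expect_equal(res$sngfr_nl_min, 1, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$sngfr_two_point, 1, tolerance = 1e-9)
})

test_that("retrograde flow and insufficient arrivals are errors", {
  s <- seq(0, 100, by = 10)
  p <- tubule_path(s = s, x = s, y = rep(0, length(s)),
                   r = rep(10, length(s)))
  expect_error(compute_sngfr(p, data.frame(s = s, t = rev(s))),
               "retrograde")
  t_few <- rep(NA_real_, length(s)); t_few[1:2] <- c(1, 2)
  expect_error(compute_sngfr(p, data.frame(s = s, t = t_few)),
               "fewer than 3")
  t_half <- seq_along(s) * 0.1
  t_half[seq(1, length(s), by = 2)] <- NA
  expect_error(compute_sngfr(p, data.frame(s = s, t = t_half)),
               "positions have detected arrivals")
})

test_that("non-monotone arrivals are flagged, not fatal", {
  s <- seq(0, 100, by = 5)
  p <- tubule_path(s = s, x = s, y = rep(0, length(s)),
                   r = rep(10, length(s)))
  t <- s / 50
  t[5] <- t[5] - 0.2
  res <- compute_sngfr(p, data.frame(s = s, t = t))
  expect_true("nonmonotone_arrivals" %in% res$flags)
})

test_that("noise-free round trip recovers snGFR within 2% across the range", {
  for (q in c(0.5, 1, 2, 4, 8)) {
    gen <- nf_nephron(q)
    path <- trace_tubule(gen$series, phantom_seeds(gen$truth, gen$phantom))
    res <- measure_sngfr(gen$series, path)
    expect_lt(abs(res$sngfr_nl_min - q) / q, 0.02)
    # two-point and regression estimators agree on uniform-radius phantoms
    expect_lt(abs(res$sngfr_two_point - res$sngfr_nl_min) /
              res$sngfr_nl_min, 0.05)
  }
})

test_that("the estimate is invariant to uniform intensity rescaling", {
  gen <- nf_nephron(4)
  path <- trace_tubule(gen$series, phantom_seeds(gen$truth, gen$phantom))
  res1 <- measure_sngfr(gen$series, path)
  scaled <- image_series(gen$series$frames * 3.7, gen$series$pixel_size,
                         gen$series$frame_interval)
  res2 <- measure_sngfr(scaled, path)
  expect_equal(res2$sngfr_nl_min, res1$sngfr_nl_min, tolerance = 1e-10)
})

test_that("noisy recovery stays within 10% median relative error", {
  # reduced-size version of the acceptance property (12 phantoms here)
  errs <- vapply(1:12, function(i) {
    q <- 0.5 + 8.5 * (i - 0.5) / 12
    ph <- nephron_phantom(true_sngfr = q, noise = TRUE, seed = 900 + i)
    gen <- generate_filling_series(ph)
    seeds <- phantom_seeds(gen$truth, ph, jitter_um = 0.5, seed = i)
    path <- trace_tubule(gen$series, seeds)
    res <- measure_sngfr(gen$series, path)
    abs(res$sngfr_nl_min - q) / q
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("tracer present at t = 0 is rejected with guidance", {
  ph <- nephron_phantom(true_sngfr = 4, bolus_time = -10, noise = FALSE)
  gen <- generate_filling_series(ph)
  cl <- gen$truth$centerline_fine
  path <- tubule_path(s = nephroflow:::arc_lengths(cl),
                      x = cl[, 1], y = cl[, 2],
                      r = gen$truth$radius_fine)
  expect_error(extract_traces(gen$series, path), "already present")
})
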