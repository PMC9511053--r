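# Generator ground truth against closed-form oracles, determinism, and
# phantom invariants.

test_that("a 1 nl tubule at 1 nl/min fills in exactly 60 s", {
  # radius 20 um => A = 400*pi; length chosen so volume = 1e6 um^3 (= 1 nl)
  len <- 1e6 / (400 * pi)
  cl <- cbind(seq(10, 10 + len, length.out = 400), 50)
  ph <- nephron_phantom(true_sngfr = 1, centerline = cl, tubule_radius = 20,
                        pixel_size = 2, n_frames = 6, noise = FALSE)
  gen <- generate_filling_series(ph)
  expect_equal(gen$truth$volume_um3, 1e6, tolerance = 1e-9)
  expect_equal(gen$truth$fill_time_s, 60, tolerance = 1e-9)
  # acquisition (6 frames) ends long before the 60 s fill: flagged, no error
  expect_true(gen$truth$truncated)
})

test_that("ground-truth front velocity matches the closed form Q / A", {
  # uniform radius 10 um at the enalapril-group control mean snGFR
  gen <- nf_nephron(4.24)
  v_expected <- (4.24e6 / 60) / (pi * 10^2)
  expect_equal(unique(round(gen$truth$velocity_um_s, 9)),
               round(v_expected, 9))
  # arrival times are t0 + s / v for constant area
  tt <- gen$truth$arrival
  expect_equal(tt$t, gen$phantom$bolus_time + tt$s / v_expected,
               tolerance = 1e-8)
})

test_that("arrival times on a tapering tubule match a fine-grid integral", {
  cl <- cbind(seq(80, 230, by = 0.5), 60)
  ph <- nephron_phantom(true_sngfr = 2, centerline = cl,
                        tubule_radius = c(10, 5), noise = FALSE)
  gen <- generate_filling_series(ph)
  # independent oracle: cumulative integral of A(s)/Q on a 0.01 um grid
  s_fine <- seq(0, 150, by = 0.01)
  r_fine <- approx(c(0, 150), c(10, 5), xout = s_fine)$y
  Q <- 2e6 / 60
  t_oracle <- ph$bolus_time +
    cumsum(c(0, diff(s_fine) * (pi * r_fine[-1]^2 +
                                pi * r_fine[-length(r_fine)]^2) / 2)) / Q
  got <- approx(gen$truth$arrival$s, gen$truth$arrival$t,
                xout = c(10, 50, 100, 149))$y
  want <- approx(s_fine, t_oracle, xout = c(10, 50, 100, 149))$y
  expect_lt(max(abs(got - want) / (want - ph$bolus_time)), 1e-3)
})

test_that("generation is deterministic under a fixed seed", {
  ph <- nephron_phantom(true_sngfr = 3, n_frames = 12, seed = 42)
  a <- generate_filling_series(ph)
  b <- generate_filling_series(ph)
  expect_identical(a$series$frames, b$series$frames)
  ph2 <- nephron_phantom(true_sngfr = 3, n_frames = 12, seed = 43)
  expect_false(identical(generate_filling_series(ph2)$series$frames,
                         a$series$frames))
  # and the generator does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_filling_series(ph)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free frames are an exact function of arrival times", {
  gen <- nf_nephron(4)
  ph <- gen$phantom
  fr <- gen$series$frames
  # background pixels carry exactly the background level in every frame
  bgpix <- which(!(gen$truth$tubule_mask | gen$truth$glomerulus_mask))
  expect_identical(unique(as.numeric(fr[, , 1][bgpix])),
                   ph$background_level)
  # a mid-tubule pixel follows the logistic ramp around its arrival time
  expect_identical(fr, generate_filling_series(ph)$series$frames)
})

test_that("mean background of noisy frames converges to background_level", {
  ph <- nephron_phantom(true_sngfr = 4, n_frames = 6, seed = 11)
  gen <- generate_filling_series(ph)
  bg <- gen$series$frames[, , 1][!(gen$truth$tubule_mask |
                                   gen$truth$glomerulus_mask)]
  se <- sd(bg) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - ph$background_level), 3 * se)
})

test_that("short tubules warn about the 45 um inclusion minimum", {
  expect_warning(nephron_phantom(tubule_length = 30), "45 um")
  expect_silent(nephron_phantom(tubule_length = 45))
})

test_that("phantom invariants are enforced", {
  expect_error(nephron_phantom(true_sngfr = 0), "positive")
  expect_error(nephron_phantom(true_sngfr = -1), "positive")
  expect_error(nephron_phantom(tubule_radius = c(5, -1)), "radii")
  expect_error(nephron_phantom(frame_interval = 0), "positive")
})

# ---- vessel stacks ----

test_that("noise-free voxelization equals the analytic tube inclusion", {
  gen <- zcyl_stack(12)
  truth <- gen$truth
  vs <- gen$stack$voxel_size
  dm <- dim(gen$stack$voxels)
  # oracle: voxel centres within 6 um of the tube axis (z-aligned)
  ax <- truth$centerline[1, 1:2]
  px <- (seq_len(dm[2]) - 0.5) * vs[1]
  py <- (seq_len(dm[1]) - 0.5) * vs[2]
  d2 <- outer((py - ax[2])^2, (px - ax[1])^2, "+")
  plane_expect <- d2 <= 6^2
  for (k in c(1, 20, 40))
    expect_identical(truth$mask[, , k], plane_expect)
  # rendered intensity is exactly two-level when noise is off
  expect_setequal(unique(as.numeric(gen$stack$voxels)),
                  c(20, 170))
  # every cross-section is a disc of the nominal diameter +/- half a voxel
  area <- sum(plane_expect) * vs[1] * vs[2]
  d_eq <- 2 * sqrt(area / pi)
  expect_lt(abs(d_eq - 12), vs[1] / 2)
})

test_that("sphere ground truth carries the analytic volume", {
  ph <- vessel_phantom(diameter = 6, voxel_size = c(0.5, 0.5, 1),
                       depth = 70, sphere_center = c(40, 40, 35),
                       sphere_radius = 30, margin_um = 8, noise = FALSE)
  gen <- generate_vessel_stack(ph)
  expect_equal(gen$truth$sphere_volume_um3, 4 / 3 * pi * 30^3)
  # voxelized volume agrees with the analytic one to 2%
  vox_vol <- sum(gen$truth$mask) * prod(ph$voxel_size)
  tube_vol <- pi * 3^2 * gen$truth$tube_length_um  # small tube contribution
  expect_lt(abs(vox_vol - tube_vol - 4 / 3 * pi * 30^3) / (4 / 3 * pi * 30^3),
            0.02)
})

test_that("vessel stacks are deterministic and invariants enforced", {
  a <- zcyl_stack(10, noise = TRUE, seed = 3)
  b <- zcyl_stack(10, noise = TRUE, seed = 3)
  expect_identical(a$stack$voxels, b$stack$voxels)
  # non-integer plane count
  expect_error(vessel_phantom(depth = 100.5, voxel_size = c(0.5, 0.5, 1)),
               "integer multiple")
  # unresolvable diameter
  expect_error(vessel_phantom(diameter = 0.9, voxel_size = c(0.5, 0.5, 1)),
               "resolvable")
  # centerline leaving the stack
  cl <- cbind(10, 10, seq(-5, 50, by = 1))
  expect_error(generate_vessel_stack(
    vessel_phantom(diameter = 8, centerline = cl, depth = 60,
                   voxel_size = c(0.5, 0.5, 1))),
    "not fully inside")
})
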