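# Formats, manifest validation, pipeline bookkeeping and determinism.

test_that("TIFF + sidecar round trip preserves data and metadata", {
  ph <- nephron_phantom(true_sngfr = 2, n_frames = 5, noise = TRUE, seed = 9)
  gen <- generate_filling_series(ph)
  f <- tempfile(fileext = ".tif")
  write_series(gen$series, f)
  back <- load_series(f)
  # float32 storage: data equal to single precision
  expect_equal(back$frames, gen$series$frames, tolerance = 1e-6)
  # physical metadata round-trips bit-exactly
  expect_identical(back$pixel_size, gen$series$pixel_size)
  expect_identical(back$frame_interval, gen$series$frame_interval)
})

test_that("a 120-plane stack at 1 um z-step declares 120 um depth", {
  vox <- array(runif(10 * 12 * 120), dim = c(10, 12, 120))
  st <- vessel_stack(vox, c(0.5, 0.5, 1), role = "efferent")
  f <- tempfile(fileext = ".tif")
  write_stack(st, f)
  back <- load_stack(f)
  expect_equal(dim(back$voxels)[3] * back$voxel_size[3], 120)
  expect_identical(back$role, "efferent")
  expect_equal(back$voxels, vox, tolerance = 1e-6)
})

test_that("missing or inconsistent sidecar metadata is an error", {
  ph <- nephron_phantom(true_sngfr = 2, n_frames = 4, noise = FALSE)
  gen <- generate_filling_series(ph)
  f <- tempfile(fileext = ".tif")
  write_series(gen$series, f)
  sc <- nephroflow:::sidecar_path(f)
  meta <- yaml::read_yaml(sc)
  # frame interval removed
  yaml::write_yaml(meta[setdiff(names(meta), "frame_interval_s")], sc)
  expect_error(load_series(f), "frame_interval_s")
  # wrong kind
  meta$kind <- "z_stack"
  yaml::write_yaml(meta, sc)
  expect_error(load_series(f), "kind")
  # page count mismatch is named
  meta$kind <- "time_series"; meta$n_frames <- 7
  yaml::write_yaml(meta, sc)
  expect_error(load_series(f), "n_frames")
  expect_error(load_series(f, tempfile()), "sidecar not found")
})

test_that("the TIFF reader rejects foreign files explicitly", {
  f <- tempfile(fileext = ".tif")
  con <- file(f, "wb")
  writeBin(charToRaw("MM"), con)  # big-endian header
  writeBin(42L, con, size = 2, endian = "big")
  writeBin(8L, con, size = 4, endian = "big")
  close(con)
  expect_error(read_tiff(f), "little-endian")
  writeLines("not a tiff", f)
  expect_error(read_tiff(f), "TIFF")
})

test_that("manifests are validated", {
  td <- withr::local_tempdir()
  mf <- data.frame(animal_id = "m1", unit_id = "u1",
                   group = "placebo", session = c("before", "before"),
                   series = "a.tif", sidecar = "a.yaml", roi = "a.json")
  p <- file.path(td, "manifest.csv")
  write.csv(mf, p, row.names = FALSE)
  expect_error(load_manifest(p, check_files = FALSE), "duplicate")
  mf$session <- c("before", "after")
  write.csv(mf, p, row.names = FALSE)
  expect_error(load_manifest(p, check_files = TRUE), "missing series")
  mf$group <- "vitamins"
  write.csv(mf, p, row.names = FALSE)
  expect_error(load_manifest(p, check_files = FALSE), "invalid group")
  write.csv(mf[, -2], p, row.names = FALSE)
  expect_error(load_manifest(p, check_files = FALSE), "missing columns")
})

test_that("demo cohort: 8 nephrons x 2 sessions give 8 paired rows", {
  td <- withr::local_tempdir()
  mp <- simulate_cohort(file.path(td, "data"), n_per_group = 2, seed = 21,
                        phantom_args = list(n_frames = 50,
                                            tubule_length = 110))
  mf <- load_manifest(mp)
  expect_equal(nrow(mf), 16)  # 4 groups x 2 units x 2 sessions
  res <- run_pipeline(mp, file.path(td, "report"))
  expect_equal(res$n_failed, 0)
  expect_equal(nrow(res$cohort), 8)
  expect_true(file.exists(file.path(td, "report", "cohort.csv")))
  expect_true(file.exists(file.path(td, "report", "group_stats.csv")))
  expect_true(file.exists(file.path(td, "report", "report.md")))
  log <- readLines(file.path(td, "report", "pipeline.log"))
  expect_true(any(grepl("snGFR", log)))
  # recovered values are in a sane physiological range
  expect_true(all(res$cohort$sngfr_nl_min_before > 0.2))
  expect_true(all(res$cohort$sngfr_nl_min_before < 12))
})

test_that("pipeline reruns are byte-identical and faults are isolated", {
  td <- withr::local_tempdir()
  # two independent simulations with the same seed are identical on disk
  mp1 <- simulate_cohort(file.path(td, "d1"), n_per_group = 1,
                         groups = c("placebo", "enalapril"), seed = 77,
                         phantom_args = list(n_frames = 50,
                                             tubule_length = 110))
  mp2 <- simulate_cohort(file.path(td, "d2"), n_per_group = 1,
                         groups = c("placebo", "enalapril"), seed = 77,
                         phantom_args = list(n_frames = 50,
                                             tubule_length = 110))
  t1 <- file.path(td, "d1", "unit01_before.tif")
  t2 <- file.path(td, "d2", "unit01_before.tif")
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  # analysis reruns produce byte-identical cohort CSVs
  run_pipeline(mp1, file.path(td, "r1"))
  run_pipeline(mp1, file.path(td, "r2"))
  c1 <- file.path(td, "r1", "cohort.csv")
  c2 <- file.path(td, "r2", "cohort.csv")
  expect_identical(readBin(c1, "raw", file.size(c1)),
                   readBin(c2, "raw", file.size(c2)))
  # a missing file fails that unit only; the batch continues
  mf <- load_manifest(mp1)
  file.remove(mf$series[1])
  res <- suppressWarnings(run_pipeline(load_manifest(mp1,
                                                     check_files = FALSE),
                                       file.path(td, "r3")))
  expect_equal(res$n_failed, 1)
  expect_equal(res$failures$unit_id, mf$unit_id[1])
  done <- setdiff(unique(mf$unit_id), res$failures$unit_id)
  expect_true(all(done %in% res$cohort$unit_id |
                  length(done) > nrow(res$cohort)))
})

test_that("configuration YAML round-trips and merges defaults", {
  td <- withr::local_tempdir()
  cfg <- pipeline_config()
  cfg$sngfr$position_spacing_um <- 4
  f <- file.path(td, "cfg.yaml")
  write_config(cfg, f)
  back <- load_config(f)
  expect_equal(back$sngfr$position_spacing_um, 4)
  expect_equal(back$trace$snap_radius_um, trace_config()$snap_radius_um)
  # partial configs inherit defaults
  yaml::write_yaml(list(sngfr = list(n_baseline_frames = 3)), f)
  part <- load_config(f)
  expect_equal(part$sngfr$n_baseline_frames, 3)
  expect_equal(part$min_tubule_length_um, 45)
})

test_that("the CLI simulates, analyses and reports", {
  td <- withr::local_tempdir()
  out_tif <- file.path(td, "sim.tif")
  expect_equal(suppressMessages(nf_cli(c(
    "simulate", "nephron", "--sngfr", "3", "--length", "110",
    "--seed", "4", "--out", out_tif))), 0L)
  expect_true(file.exists(out_tif))
  res_json <- file.path(td, "res.json")
  expect_equal(suppressMessages(nf_cli(c(
    "sngfr", "--series", out_tif,
    "--roi", file.path(td, "sim_roi.json"), "--out", res_json))), 0L)
  got <- jsonlite::read_json(res_json)
  expect_lt(abs(got$sngfr_nl_min - 3) / 3, 0.1)
  # vessel route
  vtif <- file.path(td, "ves.tif")
  expect_equal(suppressMessages(nf_cli(c(
    "simulate", "vessel", "--diameter", "12", "--depth", "40",
    "--out", vtif))), 0L)
  vres <- file.path(td, "ves.json")
  expect_equal(suppressMessages(nf_cli(c(
    "vessel", "--stack", vtif, "--role", "afferent",
    "--out", vres))), 0L)
  vgot <- jsonlite::read_json(vres)
  expect_lt(abs(vgot$mean_diameter_um - 12), 1)
  expect_equal(suppressMessages(nf_cli("nonsense")), 1L)
})
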