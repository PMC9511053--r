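# Shared fixtures, generated in code and cached per test run so several
# test files can reuse the heavier phantoms.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# noise-free default nephron at a given true snGFR
nf_nephron <- function(q, ...) {
  cached(sprintf("nf_nephron_%g", q), {
    ph <- nephron_phantom(true_sngfr = q, noise = FALSE, ...)
    c(list(phantom = ph), generate_filling_series(ph))
  })
}

# straight tubule phantom: exact length and radius control
straight_nephron <- function(q = 4, radius = 10, length = 200,
                             noise = FALSE, seed = 1L, ...) {
  y0 <- 60
  cl <- cbind(seq(80, 80 + length, by = 0.5), y0)
  nephron_phantom(true_sngfr = q, centerline = cl, tubule_radius = radius,
                  noise = noise, seed = seed, ...)
}

# z-aligned cylinder stack of a given diameter (noise-free by default)
zcyl_stack <- function(diameter, voxel_size = c(0.5, 0.5, 1), depth = 40,
                       noise = FALSE, seed = 1L) {
  generate_vessel_stack(vessel_phantom(
    diameter = diameter, voxel_size = voxel_size, depth = depth,
    noise = noise, seed = seed))
}

# brute-force squared EDT oracle (physical spacing), for small masks only
bf_edt_sq <- function(mask, sp_dims) {
  dm <- dim(mask)
  out <- array(0, dm)
  idxF <- which(mask, arr.ind = TRUE)
  idxB <- which(!mask, arr.ind = TRUE)
  if (!nrow(idxB)) stop("oracle needs background voxels")
  for (r in seq_len(nrow(idxF))) {
    d2 <- ((idxF[r, 1] - idxB[, 1]) * sp_dims[1])^2 +
      ((idxF[r, 2] - idxB[, 2]) * sp_dims[2])^2 +
      ((idxF[r, 3] - idxB[, 3]) * sp_dims[3])^2
    out[idxF[r, 1], idxF[r, 2], idxF[r, 3]] <- min(d2)
  }
  out
}
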