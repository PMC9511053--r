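# Small shared numerics and validation helpers.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Cumulative trapezoidal integral of y over x, same length as x, starts at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (n == 1) return(0)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

# Arc length positions of a polyline (rows = points).
arc_lengths <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))))
}

# Resample a polyline (and optional per-point scalars) at uniform arc-length
# spacing by linear interpolation. Returns list(s, pts, ...).
resample_polyline <- function(pts, spacing, scalars = NULL) {
  pts <- as.matrix(pts)
  s <- arc_lengths(pts)
  total <- s[length(s)]
  if (total <= 0) stop("polyline has zero length")
  s_new <- seq(0, total, by = spacing)
  if (s_new[length(s_new)] < total - 1e-9) s_new <- c(s_new, total)
  out <- sapply(seq_len(ncol(pts)), function(j)
    approx(s, pts[, j], xout = s_new, rule = 2)$y)
  res <- list(s = s_new, pts = matrix(out, ncol = ncol(pts)))
  if (!is.null(scalars)) {
    res$scalars <- lapply(scalars, function(v)
      approx(s, v, xout = s_new, rule = 2)$y)
  }
  res
}

# Bilinear interpolation of image img (matrix [ny, nx], pixel (i,j) centered
# at physical ((j-0.5)*px, (i-0.5)*px)) at physical coordinates (x, y).
# Out-of-bounds queries clamp to the border pixel.
bilinear <- function(img, x, y, pixel_size) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- x / pixel_size - 0.5
  cy <- y / pixel_size - 0.5
  cx <- pmin(pmax(cx, 0), nx - 1)
  cy <- pmin(pmax(cy, 0), ny - 1)
  j0 <- pmin(floor(cx), nx - 2); i0 <- pmin(floor(cy), ny - 2)
  fx <- cx - j0; fy <- cy - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based
  img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    img[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    img[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    img[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# numerically stable log(1 + exp(x))
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
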