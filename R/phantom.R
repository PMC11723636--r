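#' Synthetic complex 2-D phantoms
#'
#' Generates complex-valued test images that stand in for fully sampled
#' short-axis cardiac MR slices, so the whole reconstruction pipeline can be
#' exercised without any external dataset.
#'
#' `kind = "cardiac"` paints a parametric ellipse scene: an elliptical torso
#' with a brighter chest-wall rim, a bright left-ventricular blood pool inside
#' a darker myocardial ring, a second (right-ventricle-like) blood-pool
#' ellipse, and a few small internal structures. Ellipse centers, axes,
#' orientations and intensities are independently jittered per seed so every
#' seed yields a distinct but anatomically similar image. `kind =
#' "shepp_logan"` renders the classical modified Shepp-Logan head phantom
#' (additive ellipse table), with no seed jitter of the geometry.
#'
#' Both kinds carry a smooth second-order polynomial phase with seed-drawn
#' coefficients, so the real and imaginary channels are non-trivial. The
#' magnitude lies in [0, 1] and the background (outside the torso/skull) is
#' exactly zero.
#'
#' @param shape Integer vector `(nx, ny)`; both must be even and >= 32.
#' @param seed Integer seed; the phantom is a pure function of
#'   `(shape, seed, kind)`.
#' @param kind `"cardiac"` (default) or `"shepp_logan"`.
#' @return An object of class `phantom`: list with `image` (complex `nx` x
#'   `ny` matrix), `shape`, `seed`, `kind`.
#' @examples
#' p <- make_phantom(c(64, 64), seed = 7)
#' range(Mod(p$image))
#' @export
make_phantom <- function(shape, seed = 0L, kind = c("cardiac", "shepp_logan")) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L) || any(shape %% 2L != 0L)) {
    stop("shape must be two even integers >= 32, got (",
         paste(shape, collapse = ", "), ")", call. = FALSE)
  }
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    mag <- switch(kind,
                  cardiac = .cardiac_magnitude(shape),
                  shepp_logan = .shepp_logan_magnitude(shape))
    phase <- .poly_phase(shape)
  })
  structure(list(image = mag * exp(1i * phase), shape = shape,
                 seed = seed, kind = kind),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> kind=%s %dx%d seed=%d, |image| in [%.3f, %.3f]\n",
              x$kind, x$shape[1], x$shape[2], x$seed,
              min(Mod(x$image)), max(Mod(x$image))))
  invisible(x)
}

# Normalized pixel-center coordinates: x along columns, y along rows (top
# row y = +1 edge), both spanning (-1, 1).
.grid_xy <- function(shape) {
  nx <- shape[1]; ny <- shape[2]
  y <- -(seq_len(nx) - (nx / 2 + 0.5)) / (nx / 2)
  x <- (seq_len(ny) - (ny / 2 + 0.5)) / (ny / 2)
  list(x = matrix(x, nx, ny, byrow = TRUE), y = matrix(y, nx, ny))
}

# Inside-ellipse indicator for center (x0, y0), semi-axes (a, b), rotation
# phi (radians, counter-clockwise).
.in_ellipse <- function(g, x0, y0, a, b, phi = 0) {
  xr <- (g$x - x0) * cos(phi) + (g$y - y0) * sin(phi)
  yr <- -(g$x - x0) * sin(phi) + (g$y - y0) * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

.cardiac_magnitude <- function(shape) {
  g <- .grid_xy(shape)
  j <- function(s) stats::runif(1, -s, s)     # jitter helper
  jf <- function(s = 0.1) 1 + j(s)            # multiplicative jitter
  mag <- matrix(0, shape[1], shape[2])

  # torso with chest-wall rim (rim = outer minus inner ellipse)
  ta <- 0.92 * jf(0.04); tb <- 0.78 * jf(0.04); tx <- j(0.02); ty <- j(0.02)
  torso <- .in_ellipse(g, tx, ty, ta, tb)
  mag[torso] <- 0.30 * jf()
  rim_in <- .in_ellipse(g, tx, ty, ta - 0.10, tb - 0.10)
  mag[torso & !rim_in] <- 0.55 * jf()

  # right-ventricle-like blood pool (flattened ellipse left of center)
  rv <- .in_ellipse(g, -0.28 + j(0.04), 0.05 + j(0.04),
                    0.28 * jf(), 0.16 * jf(), 0.5 + j(0.3))
  mag[rv & rim_in] <- 0.85 * jf(0.05)

  # left ventricle: darker myocardial ring around a bright blood pool
  lx <- 0.12 + j(0.05); ly <- 0.02 + j(0.05)
  myo_r <- 0.30 * jf(0.08)
  pool_r <- myo_r * (0.62 * jf(0.08))
  myo <- .in_ellipse(g, lx, ly, myo_r, myo_r * jf(0.05), j(0.3))
  mag[myo] <- 0.18 * jf()
  pool <- .in_ellipse(g, lx, ly, pool_r, pool_r * jf(0.05), 0)
  mag[pool] <- 0.95 * jf(0.05)

  # papillary-muscle-like dots inside the pool, plus a descending-aorta dot
  for (k in 1:2) {
    ang <- stats::runif(1, 0, 2 * pi)
    dot <- .in_ellipse(g, lx + 0.5 * pool_r * cos(ang),
                       ly + 0.5 * pool_r * sin(ang),
                       0.035 * jf(), 0.035 * jf())
    mag[dot & pool] <- 0.25 * jf()
  }
  ao <- .in_ellipse(g, 0.05 + j(0.04), -0.45 + j(0.04), 0.07 * jf(),
                    0.07 * jf())
  mag[ao & rim_in] <- 0.80 * jf(0.05)

  pmin(pmax(mag, 0), 1)
}

# Modified Shepp-Logan ellipse table: additive intensity, semi-axes (a, b),
# center (x0, y0), rotation (degrees).
.shepp_logan_table <- matrix(c(
   1.0, 0.69,   0.92,   0,     0,      0,
  -0.8, 0.6624, 0.874,  0,    -0.0184, 0,
  -0.2, 0.11,   0.31,   0.22,  0,    -18,
  -0.2, 0.16,   0.41,  -0.22,  0,     18,
   0.1, 0.21,   0.25,   0,     0.35,   0,
   0.1, 0.046,  0.046,  0,     0.1,    0,
   0.1, 0.046,  0.046,  0,    -0.1,    0,
   0.1, 0.046,  0.023, -0.08, -0.605,  0,
   0.1, 0.023,  0.023,  0,    -0.606,  0,
   0.1, 0.023,  0.046,  0.06, -0.605,  0), ncol = 6, byrow = TRUE)

.shepp_logan_magnitude <- function(shape) {
  g <- .grid_xy(shape)
  mag <- matrix(0, shape[1], shape[2])
  for (r in seq_len(nrow(.shepp_logan_table))) {
    e <- .shepp_logan_table[r, ]
    mag <- mag + e[1] * .in_ellipse(g, e[4], e[5], e[2], e[3],
                                    e[6] * pi / 180)
  }
  pmin(pmax(mag, 0), 1)
}

# Smooth second-order polynomial phase with seed-drawn coefficients;
# total variation across the FOV on the order of +-pi.
.poly_phase <- function(shape) {
  g <- .grid_xy(shape)
  co <- stats::runif(6, -1, 1)
  co[1] * pi / 2 + co[2] * g$x + co[3] * g$y +
    co[4] * g$x^2 + co[5] * g$x * g$y + co[6] * g$y^2
}
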