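#' Receiver-array geometry for simulated coil maps
#'
#' Describes `n_coils` circular surface-coil loops placed uniformly on a ring
#' around the field of view. Defaults follow the usual simulated-array
#' convention: ring radius `0.6 * nx` pixels, loop radius `0.25 * nx` pixels,
#' loop planes parallel to the image plane at a standoff of half the loop
#' radius (so the wire never intersects the image plane and the Biot-Savart
#' field is finite everywhere).
#'
#' @param n_coils Number of loops (>= 1).
#' @param nx Grid size used to scale the default radii (pixels).
#' @param ring_radius Distance of loop centers from the FOV center, pixels.
#' @param loop_radius Loop radius, pixels; must be > 0.
#' @param angular_offsets Angles (radians) of the loop centers; defaults to
#'   `n_coils` uniformly spaced angles starting at 0.
#' @param standoff Out-of-plane offset of the loop plane, pixels.
#' @return An object of class `coil_geometry`.
#' @export
coil_geometry <- function(n_coils = 8L, nx = 256L,
                          ring_radius = 0.6 * nx,
                          loop_radius = 0.25 * nx,
                          angular_offsets = NULL,
                          standoff = loop_radius / 2) {
  n_coils <- as.integer(n_coils)
  stopifnot(n_coils >= 1L)
  if (loop_radius <= 0) stop("loop_radius must be > 0", call. = FALSE)
  if (is.null(angular_offsets)) {
    angular_offsets <- 2 * pi * (seq_len(n_coils) - 1L) / n_coils
  }
  stopifnot(length(angular_offsets) == n_coils)
  centers <- cbind(ring_radius * cos(angular_offsets),
                   ring_radius * sin(angular_offsets))
  if (anyDuplicated(round(centers, 9))) {
    stop("coil loop centers must be distinct", call. = FALSE)
  }
  structure(list(n_coils = n_coils, ring_radius = ring_radius,
                 loop_radius = loop_radius,
                 angular_offsets = angular_offsets, standoff = standoff),
            class = "coil_geometry")
}

#' @export
print.coil_geometry <- function(x, ...) {
  cat(sprintf(
    "<coil_geometry> %d loops, ring radius %.1f px, loop radius %.1f px, standoff %.1f px\n",
    x$n_coils, x$ring_radius, x$loop_radius, x$standoff))
  invisible(x)
}

#' Simulated coil sensitivity maps via the Biot-Savart law
#'
#' Each loop is discretized into `n_segments` straight current elements and
#' the magnetic field at every pixel (in the z = 0 image plane) is summed by
#' the Biot-Savart integral `dB = dl x r / |r|^3`. The complex sensitivity of
#' a coil is taken as the rotating-frame receive field `Bx - i*By` of its
#' loop, giving each raw map a smooth magnitude that peaks near the loop and
#' a smooth spatial phase. The stack is then jointly normalized so that the
#' root sum of squares over coils is exactly 1 at every pixel.
#'
#' @param geometry A [coil_geometry()].
#' @param shape Integer `(nx, ny)` grid size.
#' @param n_segments Number of straight segments per loop (>= 64).
#' @return An object of class `sensitivity_maps`: list with `maps` (complex
#'   array `nx` x `ny` x `n_coils`) and `geometry`.
#' @examples
#' s <- biot_savart_maps(coil_geometry(8, nx = 64), c(64, 64))
#' max(abs(apply(abs(s$maps)^2, c(1, 2), sum) - 1))  # ~1e-16
#' @export
biot_savart_maps <- function(geometry, shape, n_segments = 64L) {
  stopifnot(inherits(geometry, "coil_geometry"))
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 2L), n_segments >= 64L)
  if (geometry$loop_radius <= 0) stop("loop_radius must be > 0", call. = FALSE)

  nx <- shape[1]; ny <- shape[2]
  # pixel coordinates centered on the FOV, in pixel units
  px <- matrix(seq_len(ny) - (ny / 2 + 0.5), nx, ny, byrow = TRUE)
  py <- matrix(-(seq_len(nx) - (nx / 2 + 0.5)), nx, ny)

  theta <- 2 * pi * (seq_len(n_segments) - 0.5) / n_segments
  dtheta <- 2 * pi / n_segments
  maps <- array(0i, dim = c(nx, ny, geometry$n_coils))
  for (ci in seq_len(geometry$n_coils)) {
    ang <- geometry$angular_offsets[ci]
    cx <- geometry$ring_radius * cos(ang)
    cy <- geometry$ring_radius * sin(ang)
    # loop in a plane parallel to the image plane at z = standoff
    lx <- cx + geometry$loop_radius * cos(theta)
    ly <- cy + geometry$loop_radius * sin(theta)
    dlx <- -geometry$loop_radius * sin(theta) * dtheta
    dly <- geometry$loop_radius * cos(theta) * dtheta
    bx <- matrix(0, nx, ny); by <- matrix(0, nx, ny)
    for (s in seq_len(n_segments)) {
      rx <- px - lx[s]; ry <- py - ly[s]; rz <- -geometry$standoff
      r3 <- (rx^2 + ry^2 + rz^2)^1.5
      # dl = (dlx, dly, 0); dl x r = (dly*rz, -dlx*rz, dlx*ry - dly*rx)
      bx <- bx + dly[s] * rz / r3
      by <- by - dlx[s] * rz / r3
    }
    maps[, , ci] <- complex(real = bx, imaginary = -by)
  }
  rss <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  if (any(rss == 0)) stop("degenerate geometry: zero field at some pixel",
                          call. = FALSE)
  maps <- maps / as.vector(rss)   # recycles over the coil dimension
  structure(list(maps = maps, geometry = geometry),
            class = "sensitivity_maps")
}

#' @export
print.sensitivity_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<sensitivity_maps> %d coils over %dx%d grid\n", d[3], d[1],
              d[2]))
  invisible(x)
}

#' Expand a composite image into simulated multi-coil data
#'
#' Applies the multi-coil forward model: coil image `i` is the pixel-wise
#' product `S_i * image`, and coil k-space is its centered orthonormal Fourier
#' transform. Because the maps are unit-RSS, the root sum of squares of the
#' coil images reproduces `|image|` exactly.
#'
#' @param image Complex `nx` x `ny` matrix (the composite image).
#' @param maps A [sensitivity_maps()] object of matching grid size.
#' @return An object of class `multicoil_data`: `coil_images` and
#'   `coil_kspace` (complex `nx` x `ny` x `n_coils` arrays) plus `maps`.
#' @export
expand_to_coils <- function(image, maps) {
  stopifnot(inherits(maps, "sensitivity_maps"))
  d <- dim(maps$maps)
  if (!identical(dim(image), d[1:2])) {
    stop("shape mismatch: image is ", paste(dim(image), collapse = "x"),
         " but maps are ", paste(d[1:2], collapse = "x"), call. = FALSE)
  }
  n_coils <- d[3]
  coil_images <- array(0i, dim = d)
  coil_kspace <- array(0i, dim = d)
  for (ci in seq_len(n_coils)) {
    coil_images[, , ci] <- maps$maps[, , ci] * image
    coil_kspace[, , ci] <- fft2c(coil_images[, , ci])
  }
  structure(list(coil_images = coil_images, coil_kspace = coil_kspace,
                 maps = maps, geometry = maps$geometry),
            class = "multicoil_data")
}
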