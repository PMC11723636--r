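#' Acquired (undersampled) multi-coil k-space
#'
#' Bundles the zero-filled per-coil k-space measurements with the sampling
#' mask that produced them. This is the measurement object every
#' reconstructor consumes.
#'
#' @param coil_kspace_acq Complex array `nx` x `ny` x `n_coils`, zero at all
#'   unsampled positions.
#' @param mask The [vd_mask()] used for acquisition.
#' @return An object of class `acquired_data`.
#' @export
acquired_data <- function(coil_kspace_acq, mask) {
  stopifnot(inherits(mask, "sampling_mask"), length(dim(coil_kspace_acq)) == 3L)
  d <- dim(coil_kspace_acq)
  if (!identical(d[1:2], dim(mask$mask2d))) {
    stop("shape mismatch between k-space (", paste(d[1:2], collapse = "x"),
         ") and mask (", paste(dim(mask$mask2d), collapse = "x"), ")",
         call. = FALSE)
  }
  off <- which(mask$mask2d == 0)
  for (ci in seq_len(d[3])) {
    sl <- coil_kspace_acq[, , ci]
    if (any(sl[off] != 0)) {
      stop("acquired k-space must be zero at unsampled positions",
           call. = FALSE)
    }
  }
  structure(list(coil_kspace_acq = coil_kspace_acq, mask = mask),
            class = "acquired_data")
}

#' Retrospectively undersample simulated multi-coil data
#'
#' @param mc A [expand_to_coils()] result (fully sampled multi-coil data).
#' @param mask A [vd_mask()] matching the grid.
#' @return An `acquired_data` object.
#' @export
acquire <- function(mc, mask) {
  stopifnot(inherits(mc, "multicoil_data"))
  d <- dim(mc$coil_kspace)
  acq <- array(0i, dim = d)
  for (ci in seq_len(d[3])) {
    acq[, , ci] <- undersample(mc$coil_kspace[, , ci], mask)
  }
  acquired_data(acq, mask)
}

#' Walsh adaptive estimation of coil sensitivity maps
#'
#' For every pixel, the local sample correlation matrix of the coil images
#' over a `block_size` x `block_size` neighborhood is formed and its principal
#' eigenvector (computed by vectorized power iteration, initialized from the
#' center coil vector) is taken as the sensitivity vector. Eigenvector phase
#' is referenced to coil 1 so combined images have a deterministic phase, and
#' the stack is normalized to unit root sum of squares per pixel.
#'
#' @param coil_images Complex array `nx` x `ny` x `n_coils` (typically
#'   zero-filled coil images, or inverse transforms of the fully sampled
#'   calibration band).
#' @param block_size Odd neighborhood size, default 7.
#' @param n_iter Power-iteration count.
#' @return A `sensitivity_maps` object (with `geometry = NULL`).
#' @export
walsh_maps <- function(coil_images, block_size = 7L, n_iter = 40L) {
  d <- dim(coil_images)
  stopifnot(length(d) == 3L)
  block_size <- as.integer(block_size)
  if (block_size < 1L || block_size %% 2L == 0L) {
    stop("block_size must be odd and >= 1", call. = FALSE)
  }
  if (block_size > min(d[1:2])) {
    stop("block_size (", block_size, ") exceeds image size (",
         paste(d[1:2], collapse = "x"), ")", call. = FALSE)
  }
  nc <- d[3]; np <- d[1] * d[2]
  # R[i,j](p) = boxsum over block of c_i(q) * conj(c_j(q)); Hermitian, so
  # only the upper triangle is filtered.
  R <- vector("list", nc * nc)
  dim(R) <- c(nc, nc)
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      prod_ij <- .box_sum(coil_images[, , i] * Conj(coil_images[, , j]),
                          block_size)
      R[[i, j]] <- prod_ij
      if (j > i) R[[j, i]] <- Conj(prod_ij)
    }
  }
  # power iteration, vectorized over pixels: v is nc x np
  v <- matrix(0i, nc, np)
  for (i in seq_len(nc)) v[i, ] <- as.vector(coil_images[, , i])
  nv <- sqrt(colSums(abs(v)^2))
  zero_init <- nv == 0
  v[1, zero_init] <- 1          # arbitrary deterministic start where signal is 0
  nv[zero_init] <- 1
  v <- sweep(v, 2, nv, "/")
  for (it in seq_len(n_iter)) {
    w <- matrix(0i, nc, np)
    for (i in seq_len(nc)) {
      acc <- complex(length.out = np)
      for (j in seq_len(nc)) {
        acc <- acc + as.vector(R[[i, j]]) * v[j, ]
      }
      w[i, ] <- acc
    }
    nv <- sqrt(colSums(abs(w)^2))
    nv[nv == 0] <- 1
    v <- sweep(w, 2, nv, "/")
  }
  # pixels with an identically zero correlation block get a deterministic
  # unit vector so the stack stays unit-RSS everywhere
  dead <- colSums(abs(v)) == 0
  if (any(dead)) v[1, dead] <- 1
  # phase-reference to coil 1 and normalize to unit RSS (already unit norm)
  ph <- v[1, ]
  ph <- ifelse(abs(ph) > 0, ph / abs(ph), 1 + 0i)
  v <- sweep(v, 2, Conj(ph), "*")
  maps <- array(0i, dim = d)
  for (i in seq_len(nc)) maps[, , i] <- matrix(v[i, ], d[1], d[2])
  structure(list(maps = maps, geometry = NULL, block_size = block_size),
            class = "sensitivity_maps")
}

# Zero-padded moving block sum over a b x b window (separable cumsum).
.box_sum <- function(x, b) {
  h <- (b - 1L) %/% 2L
  x <- .run_sum(x, h)          # over rows
  t(.run_sum(t(x), h))         # over columns
}

.run_sum <- function(x, h) {
  if (h == 0L) return(x)
  n <- nrow(x)
  cs <- apply(x, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  hi <- pmin(seq_len(n) + h, n)
  lo <- seq_len(n) - h - 1L
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 1L
  out[pos, ] <- out[pos, , drop = FALSE] - cs[lo[pos], , drop = FALSE]
  out
}

#' Matched-filter (adaptive) coil combination
#'
#' Combines coil images into one composite image as `sum_i conj(S_i) * c_i`.
#' With unit-RSS maps no denominator is needed, and for `c_i = S_i * m` the
#' combination returns `m` exactly.
#'
#' @param coil_images Complex array `nx` x `ny` x `n_coils`.
#' @param maps A `sensitivity_maps` object of matching dimensions.
#' @return Complex `nx` x `ny` composite image.
#' @export
adaptive_combine <- function(coil_images, maps) {
  stopifnot(inherits(maps, "sensitivity_maps"))
  if (!identical(dim(coil_images), dim(maps$maps))) {
    stop("shape mismatch: coil images ",
         paste(dim(coil_images), collapse = "x"), " vs maps ",
         paste(dim(maps$maps), collapse = "x"), call. = FALSE)
  }
  d <- dim(coil_images)
  out <- matrix(0i, d[1], d[2])
  for (ci in seq_len(d[3])) {
    out <- out + Conj(maps$maps[, , ci]) * coil_images[, , ci]
  }
  out
}

#' Single-coil data consistency
#'
#' Hard replacement of estimated k-space by the measured values at sampled
#' positions: `out = acq` where the mask is 1, `k_est` elsewhere. A soft
#' variant `(k_est + weight * acq) / (1 + weight)` at sampled positions is
#' available via `weight < Inf`.
#'
#' @param k_est Estimated complex k-space matrix.
#' @param acq Acquired (zero-filled) k-space matrix, zero off-mask.
#' @param mask A `sampling_mask`.
#' @param weight Data-consistency weight; `Inf` (default) = hard replacement.
#' @return The corrected k-space matrix.
#' @export
dc_single <- function(k_est, acq, mask, weight = Inf) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (!identical(dim(k_est), dim(acq)) ||
      !identical(dim(k_est), dim(mask$mask2d))) {
    stop("shape mismatch among k_est, acq and mask", call. = FALSE)
  }
  m <- mask$mask2d
  if (is.infinite(weight)) {
    k_est * (1 - m) + acq * m
  } else {
    k_est * (1 - m) + m * (k_est + weight * acq) / (1 + weight)
  }
}

#' Multi-coil data consistency (MCDC)
#'
#' Projects a composite image onto the acquired measurements: the image is
#' multiplied by each sensitivity map, transformed to k-space, corrected by
#' per-coil hard data consistency against the measurements, transformed back,
#' and recombined by [adaptive_combine()]. With the true simulation maps this
#' operator is idempotent and leaves acquired samples exactly in place.
#'
#' @param composite Complex `nx` x `ny` image (e.g. a network output).
#' @param maps `sensitivity_maps` used for projection and recombination.
#' @param acquired An [acquired_data()] object.
#' @param weight Data-consistency weight passed to [dc_single()].
#' @return The corrected composite image.
#' @export
mcdc <- function(composite, maps, acquired, weight = Inf) {
  stopifnot(inherits(maps, "sensitivity_maps"),
            inherits(acquired, "acquired_data"))
  d <- dim(maps$maps)
  da <- dim(acquired$coil_kspace_acq)
  if (!identical(d, da)) {
    stop("coil-count/grid mismatch: maps ", paste(d, collapse = "x"),
         " vs acquired ", paste(da, collapse = "x"), call. = FALSE)
  }
  if (!identical(dim(composite), d[1:2])) {
    stop("composite image shape mismatch", call. = FALSE)
  }
  corrected <- array(0i, dim = d)
  for (ci in seq_len(d[3])) {
    k_i <- fft2c(maps$maps[, , ci] * composite)
    k_i <- dc_single(k_i, acquired$coil_kspace_acq[, , ci], acquired$mask,
                     weight)
    corrected[, , ci] <- ifft2c(k_i)
  }
  adaptive_combine(corrected, maps)
}
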