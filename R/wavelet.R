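# Orthonormal periodized 2-D Daubechies-4 (8-tap) wavelet transform.
# Implemented directly (analysis = circulant filter + downsample, synthesis =
# its adjoint); with these quadrature-mirror filters the transform is
# orthogonal, so the round trip is exact and Parseval holds. Used as the
# sparsity operator of the compressed-sensing baseline.

# 8-tap db4 decomposition filters (scaling, wavelet)
.db4_lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
             -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
             0.7148465705529157, 0.2303778133088965)
.db4_hi <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
             -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
             -0.0328830116668852, -0.010597401785069032)

# Per-size analysis matrices are cached: rows 1..N/2 are even translates of
# the low-pass filter, rows N/2+1..N of the high-pass filter.
.dwt_cache <- new.env(parent = emptyenv())

.dwt_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  if (n %% 2L != 0L || n < length(.db4_lo)) {
    stop("wavelet level requires even size >= 8, got ", n, call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    pos <- ((2L * (i - 1L) + seq_along(.db4_lo) - 1L) %% n) + 1L
    A[i, pos] <- A[i, pos] + .db4_lo
    A[n / 2 + i, pos] <- A[n / 2 + i, pos] + .db4_hi
  }
  .dwt_cache[[key]] <- A
  A
}

#' Orthonormal periodized 2-D db4 wavelet transform
#'
#' `dwt2()` returns a coefficient matrix of the same size as the input, with
#' the level-`levels` approximation in the top-left corner (octave layout);
#' `idwt2()` inverts it exactly. The transform is orthogonal: energy is
#' preserved and the inverse is the adjoint. Real and complex inputs are
#' supported (the filters are real).
#'
#' @param x 2-D matrix with both dimensions divisible by `2^levels`.
#' @param w Coefficient matrix from `dwt2()`.
#' @param levels Number of decomposition levels (default 3).
#' @return Matrix of wavelet coefficients (`dwt2`) or the reconstructed
#'   matrix (`idwt2`).
#' @export
dwt2 <- function(x, levels = 3L) {
  d <- dim(x)
  if (any(d %% 2L^levels != 0L)) {
    stop("dims (", paste(d, collapse = "x"), ") must be divisible by 2^",
         levels, call. = FALSE)
  }
  w <- x
  nr <- d[1]; nc <- d[2]
  for (l in seq_len(levels)) {
    blk <- w[seq_len(nr), seq_len(nc), drop = FALSE]
    blk <- .dwt_matrix(nr) %*% blk          # columns
    blk <- blk %*% t(.dwt_matrix(nc))       # rows
    w[seq_len(nr), seq_len(nc)] <- blk
    nr <- nr %/% 2L; nc <- nc %/% 2L
  }
  w
}

#' @rdname dwt2
#' @export
idwt2 <- function(w, levels = 3L) {
  d <- dim(w)
  nr <- d[1] %/% 2L^(levels - 1L); nc <- d[2] %/% 2L^(levels - 1L)
  x <- w
  for (l in seq_len(levels)) {
    blk <- x[seq_len(nr), seq_len(nc), drop = FALSE]
    blk <- t(.dwt_matrix(nr)) %*% blk
    blk <- blk %*% .dwt_matrix(nc)
    x[seq_len(nr), seq_len(nc)] <- blk
    nr <- nr * 2L; nc <- nc * 2L
  }
  x
}

# complex soft-thresholding (magnitude shrinkage)
.soft <- function(z, t) {
  m <- Mod(z)
  shrink <- pmax(1 - t / pmax(m, .Machine$double.eps), 0)
  z * shrink
}
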