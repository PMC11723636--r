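#' Centered orthonormal 2-D Fourier transforms
#'
#' `fft2c()` maps an image-domain array to k-space with the DC component at
#' the grid center (row `floor(Nx/2)+1`, column `floor(Ny/2)+1` in R's 1-based
#' indexing) and unitary scaling, so `ifft2c(fft2c(x))` is the identity and
#' energy is preserved (Parseval). Every k-space/image conversion in the
#' package goes through this single pair so that data-consistency equalities
#' hold exactly across modules.
#'
#' @param x A 2-D numeric or complex matrix (image domain for `fft2c`,
#'   k-space for `ifft2c`).
#' @return A complex matrix of the same dimensions.
#' @examples
#' x <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(x) {
  x <- .check_2d(x, "fft2c")
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  x <- .check_2d(x, "ifft2c")
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

.check_2d <- function(x, fname) {
  if (!is.matrix(x)) {
    if (is.array(x) || !is.atomic(x) || is.null(dim(x))) {
      stop(fname, "() requires a 2-D matrix, got ",
           paste(dim(x), collapse = "x"), call. = FALSE)
    }
  }
  if (length(dim(x)) != 2L) {
    stop(fname, "() requires a 2-D matrix", call. = FALSE)
  }
  x
}

#' Quadrant swaps placing DC at the grid center
#'
#' `fftshift2()` rotates each axis by `floor(n/2)` (DC index 1 moves to index
#' `floor(n/2)+1`); `ifftshift2()` is its inverse (they differ for odd sizes).
#'
#' @param x A 2-D matrix.
#' @return The shifted matrix.
#' @keywords internal
#' @export
fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq_len(floor(d[1] / 2)) + ceiling(d[1] / 2), seq_len(ceiling(d[1] / 2))),
    c(seq_len(floor(d[2] / 2)) + ceiling(d[2] / 2), seq_len(ceiling(d[2] / 2))),
    drop = FALSE]
}

#' @rdname fftshift2
#' @export
ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq_len(ceiling(d[1] / 2)) + floor(d[1] / 2), seq_len(floor(d[1] / 2))),
    c(seq_len(ceiling(d[2] / 2)) + floor(d[2] / 2), seq_len(floor(d[2] / 2))),
    drop = FALSE]
}
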