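#' Variable-density Cartesian undersampling mask
#'
#' Builds a 1-D variable-density random undersampling pattern over the
#' phase-encode axis (the second array axis): a fully sampled band of
#' `center_fraction * ny` lines around DC, plus randomly selected outer lines
#' drawn without replacement with probability proportional to a DC-centered
#' Gaussian density `exp(-d^2 / (2 * (sigma * ny)^2))`, where `d` is the line's
#' distance from DC. The total number of sampled lines is exactly
#' `round(ny / af_nominal)`, so the achieved acceleration is reproducible.
#' The mask is constant along the frequency-encode (first) axis.
#'
#' @param ny Number of phase-encode lines (second image dimension).
#' @param af_nominal Nominal acceleration factor, `1 < af_nominal <= ny`.
#' @param center_fraction Fraction of `ny` around DC that is always fully
#'   sampled (the self-calibration band used for Walsh sensitivity
#'   estimation). Default 1/16.
#' @param sigma Width of the Gaussian sampling density, as a fraction of
#'   `ny`. Default 0.15.
#' @param seed Integer seed; the mask is a pure function of
#'   `(ny, af_nominal, center_fraction, sigma, seed)`.
#' @param nx Number of frequency-encode rows used for the broadcast 2-D mask.
#'   Defaults to `ny`.
#' @return An object of class `sampling_mask` with elements `lines` (0/1
#'   vector of length `ny`), `mask2d` (`nx` x `ny` 0/1 matrix), and the
#'   generating parameters.
#' @examples
#' m <- vd_mask(256, af_nominal = 4, seed = 1)
#' sum(m$lines)  # exactly 64
#' @export
vd_mask <- function(ny, af_nominal, center_fraction = 1 / 16, sigma = 0.15,
                    seed = 0L, nx = ny) {
  stopifnot(is.numeric(ny), length(ny) == 1L, ny >= 2)
  if (af_nominal <= 1 || af_nominal > ny) {
    stop("af_nominal must satisfy 1 < af_nominal <= ny (got ", af_nominal, ")",
         call. = FALSE)
  }
  if (center_fraction < 0 || center_fraction > 0.5) {
    stop("center_fraction must lie in [0, 0.5]", call. = FALSE)
  }
  n_lines <- round(ny / af_nominal)
  dc <- floor(ny / 2) + 1L                 # DC line (1-based)
  d <- abs(seq_len(ny) - dc)               # distance from DC per line
  n_center <- ceiling(center_fraction * ny)
  center <- seq.int(floor((ny - n_center) / 2) + 1L, length.out = n_center)
  if (length(center) > n_lines) {
    stop("infeasible budget: center band has ", length(center),
         " lines but only ", n_lines, " lines may be sampled", call. = FALSE)
  }
  outer_budget <- n_lines - length(center)
  outer <- setdiff(seq_len(ny), center)
  w <- exp(-d[outer]^2 / (2 * (sigma * ny)^2))
  picked <- withr::with_seed(as.integer(seed), {
    outer[sample.int(length(outer), outer_budget, prob = w)]
  })
  lines <- integer(ny)
  lines[c(center, picked)] <- 1L
  structure(
    list(lines = lines,
         mask2d = matrix(lines, nrow = nx, ncol = ny, byrow = TRUE),
         af_nominal = af_nominal, center_fraction = center_fraction,
         sigma = sigma, seed = as.integer(seed), ny = as.integer(ny),
         nx = as.integer(nx)),
    class = "sampling_mask")
}

#' Construct a sampling mask from an explicit line vector
#'
#' Escape hatch for non-random patterns (full sampling, hand-picked lines) in
#' simulation studies; [vd_mask()] is the generator used for experiments.
#'
#' @param lines 0/1 vector over phase-encode lines.
#' @param nx Number of frequency-encode rows.
#' @param center_fraction Recorded center-band fraction (metadata).
#' @return A `sampling_mask`.
#' @export
as_sampling_mask <- function(lines, nx = length(lines),
                             center_fraction = 0) {
  lines <- as.integer(lines != 0)
  ny <- length(lines)
  structure(
    list(lines = lines,
         mask2d = matrix(lines, nrow = nx, ncol = ny, byrow = TRUE),
         af_nominal = if (sum(lines) > 0) ny / sum(lines) else Inf,
         center_fraction = center_fraction,
         sigma = NA_real_, seed = NA_integer_, ny = as.integer(ny),
         nx = as.integer(nx)),
    class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf(
    "<sampling_mask> ny=%d, %d/%d lines sampled (achieved AF %.2f, nominal %.2f), center_fraction=%.4g, sigma=%.3g, seed=%d\n",
    x$ny, sum(x$lines), x$ny, x$ny / sum(x$lines), x$af_nominal,
    x$center_fraction, x$sigma, x$seed))
  invisible(x)
}

#' Apply a sampling mask to k-space (zero filling)
#'
#' Multiplies k-space by the binary mask, zeroing unacquired phase-encode
#' lines. Idempotent by construction.
#'
#' @param k A 2-D complex k-space matrix.
#' @param mask A `sampling_mask` whose `mask2d` matches `dim(k)`.
#' @return The zero-filled k-space matrix.
#' @export
undersample <- function(k, mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (!identical(dim(k), dim(mask$mask2d))) {
    stop("shape mismatch: k is ", paste(dim(k), collapse = "x"),
         " but mask2d is ", paste(dim(mask$mask2d), collapse = "x"),
         call. = FALSE)
  }
  k * mask$mask2d
}

#' Save / load a sampling mask
#'
#' The line vector is written as a compact 0/1 text file and the generating
#' parameters as a JSON sidecar (`<path>.json`), so masks are portable and
#' diffable.
#'
#' @param mask A `sampling_mask`.
#' @param path File path for the line vector.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns the
#'   reconstructed `sampling_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  writeLines(paste(mask$lines, collapse = ""), path)
  meta <- mask[c("af_nominal", "center_fraction", "sigma", "seed", "ny", "nx")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("mask sidecar not found: ", meta_path, call. = FALSE)
  }
  lines <- as.integer(strsplit(readLines(path, n = 1L), "")[[1]])
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  m <- structure(
    c(list(lines = lines,
           mask2d = matrix(lines, nrow = meta$nx, ncol = meta$ny,
                           byrow = TRUE)),
      meta),
    class = "sampling_mask")
  m
}
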