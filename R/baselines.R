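#' Zero-filled reconstruction
#'
#' Inverse transform of each coil's zero-filled k-space followed by adaptive
#' coil combination. The simplest baseline: unacquired k-space stays zero, so
#' the image shows aliasing/blurring proportional to the acceleration.
#'
#' @param acquired An [acquired_data()] object.
#' @param maps `sensitivity_maps` for the combination.
#' @return Complex composite image.
#' @export
zero_filled <- function(acquired, maps) {
  stopifnot(inherits(acquired, "acquired_data"))
  .zf_composite(acquired, maps)
}

#' Compressed-sensing configuration
#'
#' @param lambda L1 regularization weight on the wavelet coefficients.
#' @param levels Wavelet decomposition levels (db4).
#' @param n_iter Maximum ISTA iterations.
#' @param step Gradient step size; must be <= 1 (the coil-weighted forward
#'   operator has unit spectral norm under unit-RSS maps).
#' @param tol Relative objective-decrease tolerance for early termination.
#' @return An object of class `cs_config`.
#' @export
cs_config <- function(lambda = 1e-3, levels = 3L, n_iter = 100L, step = 1,
                      tol = 1e-8) {
  if (step <= 0 || step > 1) stop("step must lie in (0, 1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(lambda = lambda, sparsity = "wavelet_db4",
                 levels = as.integer(levels), n_iter = as.integer(n_iter),
                 step = step, tol = tol),
            class = "cs_config")
}

#' Compressed-sensing reconstruction (wavelet ISTA)
#'
#' Solves the L1-regularized least squares problem
#' `argmin_y 1/2 * sum_i || M F(S_i y) - x_i ||^2 + lambda * || W y ||_1`
#' by proximal gradient descent (ISTA): a gradient step on the multi-coil
#' data term followed by soft-thresholding of the db4 wavelet coefficients
#' by `step * lambda`. With unit-RSS maps the data-term gradient is
#' 1-Lipschitz, so any `step <= 1` guarantees a monotonically non-increasing
#' objective. The per-iteration objective trace is returned for auditing.
#'
#' @param acquired An [acquired_data()] object.
#' @param maps `sensitivity_maps`.
#' @param config A [cs_config()].
#' @return List with `image` (complex matrix), `objective` (numeric trace),
#'   and `n_iter_run`.
#' @export
cs_reconstruct <- function(acquired, maps, config = cs_config()) {
  stopifnot(inherits(acquired, "acquired_data"),
            inherits(maps, "sensitivity_maps"))
  d <- dim(maps$maps)
  S <- maps$maps
  acq <- acquired$coil_kspace_acq
  m2 <- acquired$mask$mask2d
  lam <- config$lambda; step <- config$step; L <- config$levels

  fwd_residual <- function(y) {
    r <- array(0i, dim = d)
    for (ci in seq_len(d[3])) {
      r[, , ci] <- m2 * fft2c(S[, , ci] * y) - acq[, , ci]
    }
    r
  }
  adj <- function(r) {
    g <- matrix(0i, d[1], d[2])
    for (ci in seq_len(d[3])) {
      g <- g + Conj(S[, , ci]) * ifft2c(m2 * r[, , ci])
    }
    g
  }
  objective <- function(y, r) {
    0.5 * sum(Mod(r)^2) + if (lam > 0) lam * sum(Mod(dwt2(y, L))) else 0
  }

  y <- zero_filled(acquired, maps)
  r <- fwd_residual(y)
  obj <- objective(y, r)
  trace <- numeric(config$n_iter + 1L)
  trace[1L] <- obj
  n_run <- 0L
  for (it in seq_len(config$n_iter)) {
    z <- y - step * adj(r)
    if (lam > 0) {
      y_new <- idwt2(.soft(dwt2(z, L), step * lam), L)
    } else {
      y_new <- z
    }
    r <- fwd_residual(y_new)
    obj_new <- objective(y_new, r)
    if (!is.finite(obj_new)) {
      stop("CS objective became non-finite at iteration ", it, call. = FALSE)
    }
    y <- y_new
    n_run <- it
    trace[it + 1L] <- obj_new
    if (abs(obj - obj_new) <= config$tol * max(obj, 1)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(image = y, objective = trace[seq_len(n_run + 1L)], n_iter_run = n_run)
}

#' Single-domain U-Net baseline
#'
#' One forward pass of an image-domain network on the zero-filled composite
#' image, with no data-consistency step — the conventional deep-learning
#' baseline the cascades are compared against.
#'
#' @param acquired An [acquired_data()] object.
#' @param maps `sensitivity_maps`.
#' @param trained_inet A trained `unet` (or [passthrough_net()]).
#' @return Complex composite image.
#' @export
unet_single_domain <- function(acquired, maps, trained_inet) {
  forward_inet(zero_filled(acquired, maps), trained_inet)
}

#' Train the single-domain image U-Net baseline
#'
#' Trains an I-Net on (zero-filled composite, fully sampled composite) image
#' pairs with the same optimizer recipe and by-volume split as the cascades.
#'
#' @param dataset A [make_training_set()] result.
#' @param tconf A [train_config()].
#' @param uconf A [unet_config()].
#' @param verbose Print progress.
#' @return List with `net`, `history`, `input_val_loss`.
#' @export
train_single_domain_unet <- function(dataset, tconf = train_config(),
                                     uconf = unet_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "recon_dataset"))
  ex <- dataset$examples
  vols <- vapply(ex, `[[`, 1L, "volume")
  uv <- unique(vols)
  n_val <- max(1L, round(tconf$val_fraction * length(uv)))
  val_vols <- withr::with_seed(tconf$seed, sample(uv, n_val))
  val_idx <- which(vols %in% val_vols)
  net <- build_unet(uconf, seed = tconf$seed + 1L)
  train_unet(net, lapply(ex, `[[`, "zf_img"), lapply(ex, `[[`, "label_img"),
             val_idx, tconf, verbose = verbose)
}
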