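#' Image-quality metrics against a fully sampled reference
#'
#' All three metrics operate on magnitude images after normalizing both test
#' and reference by the reference maximum (so the reference peak is 1).
#' `rmse()` is the root mean squared magnitude error; `psnr()` is
#' `20*log10(peak/rmse)` in dB with peak 1 after normalization; `ssim()` is
#' the mean local structural similarity with the canonical 11x11 Gaussian
#' window (sigma 1.5), constants K1 = 0.01, K2 = 0.03, dynamic range 1, and
#' valid-window (cropped) aggregation.
#'
#' The reference image must itself be the adaptive coil combination of the
#' fully sampled coil images, so all reconstruction methods are scored
#' against one common reference definition.
#'
#' @param test,ref Complex or numeric matrices of equal size.
#' @return A single numeric value.
#' @export
rmse <- function(test, ref) {
  n <- .norm_pair(test, ref)
  sqrt(mean((n$test - n$ref)^2))
}

#' @rdname rmse
#' @export
psnr <- function(test, ref) {
  e <- rmse(test, ref)
  if (e == 0) return(Inf)
  20 * log10(1 / e)
}

#' @rdname rmse
#' @export
ssim <- function(test, ref) {
  n <- .norm_pair(test, ref)
  k <- .gauss_kernel(11L, 1.5)
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_x <- .filter2_valid(n$test, k); mu_y <- .filter2_valid(n$ref, k)
  xx <- .filter2_valid(n$test^2, k) - mu_x^2
  yy <- .filter2_valid(n$ref^2, k) - mu_y^2
  xy <- .filter2_valid(n$test * n$ref, k) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (xx + yy + C2))
  mean(s)
}

.norm_pair <- function(test, ref) {
  if (!identical(dim(test), dim(ref))) {
    stop("shape mismatch: test ", paste(dim(test), collapse = "x"),
         " vs ref ", paste(dim(ref), collapse = "x"), call. = FALSE)
  }
  tm <- Mod(test); rm_ <- Mod(ref)
  peak <- max(rm_)
  if (peak == 0) stop("reference image is identically zero", call. = FALSE)
  list(test = tm / peak, ref = rm_ / peak)
}

.gauss_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable valid-mode 2-D correlation with a symmetric 1-D kernel.
.filter2_valid <- function(x, k) {
  n <- length(k); m <- (n - 1L) %/% 2L
  conv_cols <- function(a) {
    nr <- nrow(a)
    out <- matrix(0, nr - n + 1L, ncol(a))
    for (j in seq_len(n)) {
      out <- out + k[j] * a[j:(nr - n + j), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

#' Evaluate a set of reconstructions
#'
#' Computes SSIM, PSNR and RMSE for each (reconstruction, reference) pair and
#' summarizes them as mean and standard deviation across images. Images with
#' infinite PSNR (exact reconstructions) are excluded from the PSNR summary
#' with a warning.
#'
#' @param recon_set,ref_set Lists of complex matrices, aligned by position.
#' @param method Method label stored in the report.
#' @param af Acceleration factor label stored in the report.
#' @param ids Optional image identifiers (default sequence numbers).
#' @return An object of class `eval_report`: `per_image` data frame and
#'   `summary` data frame (`metric`, `mean`, `sd`), plus `method`, `af`,
#'   `n_images`.
#' @export
evaluate <- function(recon_set, ref_set, method = "method", af = NA_real_,
                     ids = NULL) {
  if (length(recon_set) != length(ref_set)) {
    stop("recon_set and ref_set lengths differ (", length(recon_set), " vs ",
         length(ref_set), ")", call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_along(recon_set)
  per <- data.frame(
    id = ids,
    ssim = mapply(ssim, recon_set, ref_set),
    psnr_db = mapply(psnr, recon_set, ref_set),
    rmse = mapply(rmse, recon_set, ref_set))
  psnr_vals <- per$psnr_db
  if (any(is.infinite(psnr_vals))) {
    warning("excluding ", sum(is.infinite(psnr_vals)),
            " image(s) with infinite PSNR from the PSNR summary")
    psnr_vals <- psnr_vals[is.finite(psnr_vals)]
  }
  summ <- data.frame(
    metric = c("ssim", "psnr_db", "rmse"),
    mean = c(mean(per$ssim), mean(psnr_vals), mean(per$rmse)),
    sd = c(stats::sd(per$ssim),
           if (length(psnr_vals) > 1) stats::sd(psnr_vals) else 0,
           stats::sd(per$rmse)))
  summ$sd[is.na(summ$sd)] <- 0
  structure(list(per_image = per, summary = summ, method = method, af = af,
                 n_images = length(recon_set)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> method=%s AF=%s over %d image(s)\n", x$method,
              format(x$af), x$n_images))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %.4f +- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-image rows as CSV and the summary as JSON.
#'
#' @param report An `eval_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(cbind(method = report$method, af = report$af,
                           report$per_image), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(method = report$method, af = report$af,
           n_images = report$n_images, summary = report$summary),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}
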