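#' Build a training set of undersampled/fully-sampled example pairs
#'
#' Flattens a list of fully sampled multi-coil volumes into independent 2-D
#' examples. For each volume one variable-density mask is drawn (per-volume
#' masks by default; set `mask_per_frame = TRUE` for one mask per frame), the
#' coil k-space is retrospectively undersampled, and each example stores the
#' acquired per-coil zero-filled k-space, the zero-filled composite image and
#' k-space, and the fully sampled composite image and k-space labels. The
#' composite reference is always the adaptive combination of the fully
#' sampled coil images.
#'
#' @param volumes List of [simulate_volume()] results (or one volume).
#' @param af Nominal acceleration factor (2 or 4 in the experiments).
#' @param mask_seed Base seed for mask generation; volume `v` (frame `f`)
#'   gets a deterministically derived seed.
#' @param center_fraction,sigma Mask density parameters, see [vd_mask()].
#' @param mask_per_frame Draw a fresh mask for every frame.
#' @return An object of class `recon_dataset`: list of examples, each with
#'   `acquired`, `maps`, `zf_img`, `zf_k`, `label_img`, `label_k`, `volume`.
#' @export
make_training_set <- function(volumes, af, mask_seed = 0L,
                              center_fraction = 1 / 16, sigma = 0.15,
                              mask_per_frame = FALSE) {
  if (inherits(volumes, "multicoil_volume")) volumes <- list(volumes)
  examples <- list()
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    d <- dim(vol$kspace)
    vol_mask <- vd_mask(d[2], af, center_fraction, sigma,
                        seed = mask_seed + 7919L * (v - 1L), nx = d[1])
    for (f in seq_len(d[4])) {
      mask <- if (mask_per_frame) {
        vd_mask(d[2], af, center_fraction, sigma,
                seed = mask_seed + 7919L * (v - 1L) + f, nx = d[1])
      } else {
        vol_mask
      }
      mc <- volume_frame(vol, f)
      acq <- acquire(mc, mask)
      label_img <- adaptive_combine(mc$coil_images, vol$maps)
      zf_img <- zero_filled(acq, vol$maps)
      examples[[length(examples) + 1L]] <- list(
        acquired = acq, maps = vol$maps,
        zf_img = zf_img, zf_k = fft2c(zf_img),
        label_img = label_img, label_k = fft2c(label_img),
        volume = v)
    }
  }
  structure(list(examples = examples, af = af,
                 shape = dim(volumes[[1]]$kspace)[1:2]),
            class = "recon_dataset")
}

#' @export
print.recon_dataset <- function(x, ...) {
  cat(sprintf("<recon_dataset> %d examples (%d volumes), %dx%d, AF=%g\n",
              length(x$examples),
              length(unique(vapply(x$examples, `[[`, 1L, "volume"))),
              x$shape[1], x$shape[2], x$af))
  invisible(x)
}

#' Train a dual-domain cascade (KI or IK order)
#'
#' Incremental two-stage training. Stage 1 trains the first subnetwork in
#' its own domain (K-Net on composite zero-filled vs fully sampled k-space;
#' I-Net on zero-filled vs fully sampled images). Stage 2 freezes the first
#' subnetwork, propagates every example through it plus an MCDC projection
#' (and the domain transform the cascade order requires) to build the
#' stage-2 inputs, then trains the second subnetwork against its domain's
#' fully sampled labels. There is no joint fine-tuning. The 80/20 split is
#' made by volume, so temporally adjacent frames never straddle the split.
#'
#' @param dataset A [make_training_set()] result.
#' @param order `"KI"` (k-space net first) or `"IK"` (image net first).
#' @param tconf A [train_config()].
#' @param uconf A [unet_config()] shared by both subnetworks.
#' @param maps_policy `"true_maps"` (simulation maps, default during
#'   training) or `"walsh_from_center"` (self-calibrated maps estimated from
#'   the fully sampled center band).
#' @param verbose Print per-epoch progress.
#' @return An object of class `cascade_model` with both subnetworks, both
#'   training histories, and the stage-2 input validation loss.
#' @export
train_cascade <- function(dataset, order = c("IK", "KI"),
                          tconf = train_config(), uconf = unet_config(),
                          maps_policy = c("true_maps", "walsh_from_center"),
                          verbose = FALSE) {
  order <- match.arg(order)
  maps_policy <- match.arg(maps_policy)
  stopifnot(inherits(dataset, "recon_dataset"))
  ex <- dataset$examples
  if (length(ex) == 0L) stop("empty dataset", call. = FALSE)
  .check_divisible(c(dataset$shape, 1L, 1L), uconf$depth)

  vols <- vapply(ex, `[[`, 1L, "volume")
  uv <- unique(vols)
  n_val <- max(1L, round(tconf$val_fraction * length(uv)))
  val_vols <- withr::with_seed(tconf$seed, sample(uv, n_val))
  val_idx <- which(vols %in% val_vols)

  maps_of <- function(e) {
    if (maps_policy == "true_maps") e$maps else center_calibrated_maps(e$acquired)
  }

  # stage 1
  if (order == "KI") {
    in1 <- lapply(ex, `[[`, "zf_k");  lab1 <- lapply(ex, `[[`, "label_k")
  } else {
    in1 <- lapply(ex, `[[`, "zf_img"); lab1 <- lapply(ex, `[[`, "label_img")
  }
  net1 <- build_unet(uconf, seed = tconf$seed + 1L)
  s1 <- train_unet(net1, in1, lab1, val_idx, tconf, verbose = verbose)

  # stage 2 inputs: frozen subnet-1 inference + MCDC (+ domain transform)
  in2 <- vector("list", length(ex))
  for (i in seq_along(ex)) {
    m <- maps_of(ex[[i]])
    if (order == "KI") {
      img <- ifft2c(forward_knet(ex[[i]]$zf_k, s1$net))
      in2[[i]] <- mcdc(img, m, ex[[i]]$acquired)
    } else {
      img <- forward_inet(ex[[i]]$zf_img, s1$net)
      in2[[i]] <- fft2c(mcdc(img, m, ex[[i]]$acquired))
    }
  }
  lab2 <- if (order == "KI") lapply(ex, `[[`, "label_img") else
    lapply(ex, `[[`, "label_k")
  net2 <- build_unet(uconf, seed = tconf$seed + 2L)
  s2 <- train_unet(net2, in2, lab2, val_idx, tconf, verbose = verbose)

  structure(list(order = order, subnet1 = s1$net, subnet2 = s2$net,
                 history1 = s1$history, history2 = s2$history,
                 stage2_input_val_loss = s2$input_val_loss,
                 stage1_input_val_loss = s1$input_val_loss,
                 maps_policy = maps_policy, af = dataset$af,
                 unet_config = uconf, train_config = tconf,
                 val_volumes = sort(val_vols)),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(
    "<cascade_model> order=%s, AF=%g, maps=%s; stage losses: %.3e -> %.3e (val)\n",
    x$order, x$af, x$maps_policy,
    x$stage2_input_val_loss, min(x$history2$val_loss)))
  invisible(x)
}

#' Sensitivity maps self-calibrated from the fully sampled center band
#'
#' Zeroes all k-space lines outside the fully sampled center band, inverse
#' transforms each coil, and runs Walsh estimation on the resulting low-
#' resolution coil images. This is the map source available at inference
#' time when no simulation ground truth exists.
#'
#' @param acquired An [acquired_data()] object whose mask has a fully
#'   sampled center band.
#' @param block_size Walsh block size.
#' @return A `sensitivity_maps` object.
#' @export
center_calibrated_maps <- function(acquired, block_size = 7L) {
  stopifnot(inherits(acquired, "acquired_data"))
  mask <- acquired$mask
  ny <- mask$ny
  n_center <- ceiling(mask$center_fraction * ny)
  band <- seq.int(floor((ny - n_center) / 2) + 1L, length.out = n_center)
  d <- dim(acquired$coil_kspace_acq)
  low <- array(0i, dim = d)
  for (ci in seq_len(d[3])) {
    k <- matrix(0i, d[1], d[2])
    k[, band] <- acquired$coil_kspace_acq[, band, ci]
    low[, , ci] <- ifft2c(k)
  }
  walsh_maps(low, block_size = block_size)
}

# shared front end: zero-filled composite image of an acquisition
.zf_composite <- function(acquired, maps) {
  d <- dim(acquired$coil_kspace_acq)
  imgs <- array(0i, dim = d)
  for (ci in seq_len(d[3])) {
    imgs[, , ci] <- ifft2c(acquired$coil_kspace_acq[, , ci])
  }
  adaptive_combine(imgs, maps)
}

#' Cascade inference
#'
#' `ki_reconstruct()`: zero-filled composite k-space -> K-Net -> inverse FFT
#' -> MCDC -> I-Net -> MCDC. `ik_reconstruct()`: zero-filled composite image
#' -> I-Net -> MCDC -> FFT -> K-Net -> inverse FFT -> MCDC. With
#' pass-through subnetworks both reduce to repeated MCDC of the zero-filled
#' composite.
#'
#' @param acquired An [acquired_data()] object.
#' @param maps `sensitivity_maps` used by MCDC and the combines (true maps
#'   or [center_calibrated_maps()]).
#' @param model A `cascade_model` of the matching order, or a list with
#'   elements `subnet1`, `subnet2` (e.g. pass-through stubs) and `order`.
#' @return The reconstructed complex composite image.
#' @export
ki_reconstruct <- function(acquired, maps, model) {
  if (!identical(model$order, "KI")) {
    stop("model order is ", model$order, ", expected KI", call. = FALSE)
  }
  zf <- .zf_composite(acquired, maps)
  img <- ifft2c(forward_knet(fft2c(zf), model$subnet1))
  img <- mcdc(img, maps, acquired)
  img <- forward_inet(img, model$subnet2)
  mcdc(img, maps, acquired)
}

#' @rdname ki_reconstruct
#' @export
ik_reconstruct <- function(acquired, maps, model) {
  if (!identical(model$order, "IK")) {
    stop("model order is ", model$order, ", expected IK", call. = FALSE)
  }
  zf <- .zf_composite(acquired, maps)
  img <- forward_inet(zf, model$subnet1)
  img <- mcdc(img, maps, acquired)
  k <- forward_knet(fft2c(img), model$subnet2)
  img <- ifft2c(k)
  mcdc(img, maps, acquired)
}

#' Save / load a trained cascade
#'
#' Writes the two subnetwork checkpoints (`<prefix>_subnet1.h5`,
#' `<prefix>_subnet2.h5`, each with a JSON sidecar) plus a `<prefix>.json`
#' manifest recording order, acceleration factor and maps policy, and the two
#' per-epoch training histories as CSV.
#'
#' @param model A trained `cascade_model`.
#' @param prefix Path prefix for the files.
#' @return `save_cascade()` returns `prefix` invisibly; `load_cascade()` the
#'   reconstructed `cascade_model` (histories reloaded from CSV).
#' @export
save_cascade <- function(model, prefix) {
  stopifnot(inherits(model, "cascade_model"), inherits(model$subnet1, "unet"))
  write_checkpoint(model$subnet1, paste0(prefix, "_subnet1.h5"))
  write_checkpoint(model$subnet2, paste0(prefix, "_subnet2.h5"))
  utils::write.csv(model$history1, paste0(prefix, "_history1.csv"),
                   row.names = FALSE)
  utils::write.csv(model$history2, paste0(prefix, "_history2.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(order = model$order, af = model$af, maps_policy = model$maps_policy,
         stage1_input_val_loss = model$stage1_input_val_loss,
         stage2_input_val_loss = model$stage2_input_val_loss,
         val_volumes = model$val_volumes),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(prefix) {
  manifest <- paste0(prefix, ".json")
  if (!file.exists(manifest)) stop("cascade manifest not found: ", manifest,
                                   call. = FALSE)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  structure(list(order = meta$order,
                 subnet1 = read_checkpoint(paste0(prefix, "_subnet1.h5")),
                 subnet2 = read_checkpoint(paste0(prefix, "_subnet2.h5")),
                 history1 = utils::read.csv(paste0(prefix, "_history1.csv")),
                 history2 = utils::read.csv(paste0(prefix, "_history2.csv")),
                 stage1_input_val_loss = meta$stage1_input_val_loss,
                 stage2_input_val_loss = meta$stage2_input_val_loss,
                 maps_policy = meta$maps_policy, af = meta$af,
                 val_volumes = meta$val_volumes),
            class = "cascade_model")
}

#' Convenience stub cascade with pass-through subnetworks
#'
#' @param order `"KI"` or `"IK"`.
#' @return A minimal list usable as `model` in [ki_reconstruct()] /
#'   [ik_reconstruct()].
#' @export
passthrough_cascade <- function(order = c("IK", "KI")) {
  order <- match.arg(order)
  structure(list(order = order, subnet1 = passthrough_net(),
                 subnet2 = passthrough_net()),
            class = "cascade_model")
}
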