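#' Training configuration
#'
#' Mirrors the optimization recipe used for both subnetworks: mean-squared
#'-error loss minimized by RMSProp starting at learning rate 0.001, reduced
#' by a factor of 0.1 whenever the validation loss has not improved for
#' `lr_patience` (10) consecutive epochs, with early stopping after
#' `es_patience` (20) stale epochs, and an 80/20 train/validation split
#' (performed by volume, see [train_cascade()]).
#'
#' @param lr0 Initial learning rate.
#' @param lr_factor Multiplicative learning-rate reduction on plateau.
#' @param lr_patience Epochs without validation improvement before reducing.
#' @param es_patience Epochs without improvement before stopping early.
#' @param val_fraction Fraction of volumes held out for validation.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum epochs per training stage.
#' @param rho,eps RMSProp decay and stabilizer.
#' @param restore_best Return the weights of the best validation epoch.
#' @param seed Seed controlling the split and the shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-3, lr_factor = 0.1, lr_patience = 10L,
                         es_patience = 20L, val_fraction = 0.2,
                         batch_size = 8L, max_epochs = 30L, rho = 0.9,
                         eps = 1e-7, restore_best = TRUE, seed = 0L) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  structure(list(loss = "mse", optimizer = "rmsprop", lr0 = lr0,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 es_patience = as.integer(es_patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), rho = rho, eps = eps,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Normalize a (input, label) pair by the input's maximum magnitude and pack
# into channel tensors. Returns [H, W, 2] arrays.
.pack_pair <- function(input, label) {
  s <- max(Mod(input))
  if (s == 0) s <- 1
  list(x = complex_to_channels(input / s),
       y = complex_to_channels(label / s), scale = s)
}

# Stack a list of [H, W, 2] arrays into [H, W, 2, B].
.stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), dim = c(d, length(lst)))
}

# Mean squared error between two packed tensors.
.mse <- function(a, b) mean((a - b)^2)

#' Train one U-Net on complex (input, label) pairs
#'
#' Low-level single-network trainer used for both cascade stages and the
#' single-domain U-Net baseline. Inputs and labels are complex matrices in
#' the network's own domain; each pair is normalized to the input's maximum
#' magnitude before packing (the network always sees unit-scale data).
#'
#' The returned history records, per epoch, the training loss, the
#' validation loss (inference-mode batch statistics), and the learning rate
#' in force, so plateau-driven learning-rate reductions are auditable.
#'
#' @param net A freshly built (or partially trained) `unet`.
#' @param inputs,labels Lists of complex matrices.
#' @param val_idx Integer indices of validation examples within
#'   `inputs`/`labels` (the remaining examples are trained on).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `net` (trained), `history` (data frame: epoch, lr,
#'   train_loss, val_loss), and `input_val_loss` (the validation loss of the
#'   identity mapping, i.e. the loss the stage inherits from its input).
#' @export
train_unet <- function(net, inputs, labels, val_idx, config = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(net, "unet"), length(inputs) == length(labels),
            length(inputs) >= 2L)
  n <- length(inputs)
  val_idx <- sort(unique(as.integer(val_idx)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L || length(val_idx) == 0L) {
    stop("both training and validation sets must be non-empty", call. = FALSE)
  }
  pairs <- Map(.pack_pair, inputs, labels)
  xs <- lapply(pairs, `[[`, "x")
  ys <- lapply(pairs, `[[`, "y")
  input_val_loss <- mean(vapply(val_idx, function(i) .mse(xs[[i]], ys[[i]]),
                                numeric(1)))

  rms <- lapply(net$params, function(p) array(0, dim = dim(p) %||% length(p)))
  lr <- config$lr0
  best_val <- Inf; best_params <- net$params; best_bn <- net$bn_state
  lr_wait <- 0L; es_wait <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_loss = numeric())

  epoch_seeds <- withr::with_seed(config$seed, {
    sample.int(.Machine$integer.max - 1L, config$max_epochs)
  })

  for (epoch in seq_len(config$max_epochs)) {
    ord <- withr::with_seed(epoch_seeds[epoch], sample(tr_idx))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      xb <- .stack_batch(xs[bi]); yb <- .stack_batch(ys[bi])
      fw <- unet_forward(net, xb, train = TRUE)
      diff <- fw$y - yb
      loss <- mean(diff^2)
      ep_loss <- ep_loss + loss * length(bi); ep_n <- ep_n + length(bi)
      gy <- 2 * diff / length(diff)
      grads <- unet_backward(net, fw$cache, gy)
      net <- .rmsprop_step(net, grads, rms, lr, config$rho, config$eps)
      rms <- attr(net, "rms"); attr(net, "rms") <- NULL
      net <- .bn_update_state(net, fw$cache)
    }
    train_loss <- ep_loss / ep_n
    sq <- 0; nel <- 0
    for (chunk in split(val_idx,
                        ceiling(seq_along(val_idx) / config$batch_size))) {
      pred <- unet_forward(net, .stack_batch(xs[chunk]), train = FALSE)$y
      sq <- sq + sum((pred - .stack_batch(ys[chunk]))^2)
      nel <- nel + length(pred)
    }
    val_loss <- sq / nel
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = train_loss,
                                   val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.1e  train %.3e  val %.3e", epoch, lr,
                      train_loss, val_loss))
    }
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- net$params
      best_bn <- net$bn_state
      lr_wait <- 0L; es_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L; es_wait <- es_wait + 1L
      if (lr_wait >= config$lr_patience) {
        lr <- lr * config$lr_factor
        lr_wait <- 0L
      }
      if (es_wait >= config$es_patience) break
    }
  }
  if (config$restore_best) {
    net$params <- best_params
    net$bn_state <- best_bn
  }
  list(net = net, history = hist, input_val_loss = input_val_loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct the plateau learning-rate trace from a validation-loss log
#'
#' Replays the reduce-on-plateau rule (reduce by `factor` after `patience`
#' consecutive epochs without validation improvement) over a recorded
#' validation-loss sequence. Comparing the result with the learning rates a
#' training run actually logged verifies that the scheduler behaved as
#' configured.
#'
#' @param val_loss Numeric vector of per-epoch validation losses.
#' @param lr0 Initial learning rate.
#' @param factor Multiplicative reduction.
#' @param patience Stale epochs before a reduction.
#' @return Numeric vector: the learning rate in force at each epoch.
#' @export
expected_lr_trace <- function(val_loss, lr0 = 1e-3, factor = 0.1,
                              patience = 10L) {
  lr <- lr0; best <- Inf; wait <- 0L
  out <- numeric(length(val_loss))
  for (e in seq_along(val_loss)) {
    out[e] <- lr
    if (val_loss[e] < best) {
      best <- val_loss[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0L
      }
    }
  }
  out
}

.rmsprop_step <- function(net, grads, rms, lr, rho, eps) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    rms[[nm]] <- rho * rms[[nm]] + (1 - rho) * g^2
    net$params[[nm]] <- net$params[[nm]] - lr * g / (sqrt(rms[[nm]]) + eps)
  }
  attr(net, "rms") <- rms
  net
}

#' Save / load a network checkpoint
#'
#' Weights and batch-norm state are written as a flat HDF5 file with a JSON
#' sidecar recording the architecture configuration and initialization seed.
#'
#' @param net A `unet`.
#' @param path Checkpoint path (`.h5`).
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   the reconstructed `unet`.
#' @export
write_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "params")
  rhdf5::h5createGroup(path, "bn_state")
  for (nm in names(net$params)) {
    rhdf5::h5write(net$params[[nm]], path, paste0("params/", nm))
  }
  for (nm in names(net$bn_state)) {
    rhdf5::h5write(net$bn_state[[nm]], path, paste0("bn_state/", nm))
  }
  rhdf5::h5closeAll()
  side <- c(unclass(net$config), list(seed = net$seed))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- unet_config(n_conv3 = side$n_conv3,
                        base_filters = side$base_filters, depth = side$depth,
                        init_sd = side$init_sd, residual = side$residual,
                        bn_momentum = side$bn_momentum, bn_eps = side$bn_eps)
  net <- build_unet(config, seed = side$seed)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (nm in names(net$params)) {
    v <- rhdf5::h5read(path, paste0("params/", nm))
    if (is.matrix(net$params[[nm]])) {
      net$params[[nm]] <- matrix(v, nrow = nrow(net$params[[nm]]))
    } else {
      net$params[[nm]] <- as.numeric(v)
    }
  }
  for (nm in names(net$bn_state)) {
    net$bn_state[[nm]] <- as.numeric(rhdf5::h5read(path,
                                                   paste0("bn_state/", nm)))
  }
  net
}
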