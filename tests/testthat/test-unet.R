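test_that("complex/channel packing is an exact bijection", {
  z <- rand_complex(16, seed = 2)
  t <- complex_to_channels(z)
  expect_identical(dim(t), c(16L, 16L, 2L))
  expect_identical(channels_to_complex(t), z)
  zc <- matrix(3 + 4i, 8, 8)
  tc <- complex_to_channels(zc)
  expect_true(all(tc[, , 1] == 3) && all(tc[, , 2] == 4))
  zr <- matrix(1.5, 8, 8) + 0i
  expect_true(all(complex_to_channels(zr)[, , 2] == 0))
  expect_error(channels_to_complex(array(0, c(8, 8, 3))), "channel-packed")
})

test_that("the default architecture satisfies the stated layer census", {
  net <- build_unet(unet_config(base_filters = 4), seed = 1)
  census <- unet_layer_census(net)
  expect_identical(census$conv3, 10L)   # 4 encoder + 2 bottleneck + 4 decoder
  expect_identical(census$conv1, 1L)    # final 1x1 layer
  # every 3x3 conv is followed by ReLU then BN; the 1x1 conv by BN alone
  types <- vapply(net$ops, `[[`, "", "type")
  conv_pos <- which(types == "conv")
  for (i in conv_pos) {
    K <- net$ops[[i]]$K
    if (K == 3) {
      expect_identical(types[i + 1L], "relu")
      expect_identical(types[i + 2L], "bn")
    } else {
      expect_identical(types[i + 1L], "bn")
    }
  }
  expect_error(unet_config(n_conv3 = 9), "n_conv3")
  expect_error(unet_config(n_conv3 = 12, depth = 2), "n_conv3")
})

test_that("convolutions are bias-free with seed-controlled normal init", {
  net <- build_unet(unet_config(base_filters = 8, init_sd = 0.05), seed = 3)
  expect_identical(build_unet(unet_config(base_filters = 8), seed = 3)$params,
                   net$params)
  w <- unlist(net$params[grep("^w", names(net$params))])
  expect_equal(stats::sd(w), 0.05, tolerance = 0.02)
  expect_equal(mean(w), 0, tolerance = 0.005)
  # no bias parameters exist
  expect_false(any(grepl("bias", names(net$params))))
})

test_that("parameter count grows with base_filters and shapes are preserved", {
  n8 <- unet_n_params(build_unet(unet_config(base_filters = 8), seed = 1))
  n16 <- unet_n_params(build_unet(unet_config(base_filters = 16), seed = 1))
  expect_gt(n16, n8)
  net <- build_unet(unet_config(base_filters = 4), seed = 1)
  x <- array(rnorm(64 * 64 * 2), dim = c(64, 64, 2, 1))
  y <- mricascade:::unet_forward(net, x)$y
  expect_identical(dim(y), dim(x))
  expect_error(mricascade:::unet_forward(net, array(0, c(30, 30, 2, 1))),
               "divisible")
})

test_that("inference is deterministic and finite on unit-scale inputs", {
  net <- build_unet(unet_config(base_filters = 4, residual = FALSE), seed = 9)
  k <- rand_complex(32, seed = 4)
  k <- k / max(Mod(k))
  o1 <- forward_knet(k, net)
  o2 <- forward_knet(k, net)
  expect_identical(o1, o2)
  expect_true(all(is.finite(Mod(o1))))
  expect_identical(dim(o1), dim(k))
  # pass-through stub
  expect_identical(forward_inet(k, passthrough_net()), k)
})

test_that("backpropagation matches finite differences", {
  net <- build_unet(unet_config(n_conv3 = 6, base_filters = 2, depth = 1,
                                init_sd = 0.3), seed = 42)
  withr::with_seed(9, {
    x <- array(stats::rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
    lab <- array(stats::rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
  })
  lossfun <- function(nt) {
    mean((mricascade:::unet_forward(nt, x, train = TRUE)$y - lab)^2)
  }
  fw <- mricascade:::unet_forward(net, x, train = TRUE)
  grads <- mricascade:::unet_backward(net, fw$cache,
                                      2 * (fw$y - lab) / length(fw$y))
  errs <- c()
  withr::with_seed(11, {
    for (nm in names(grads)) {
      for (i in sample(length(grads[[nm]]), min(4, length(grads[[nm]])))) {
        np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + 1e-6
        nmn <- net; nmn$params[[nm]][i] <- nmn$params[[nm]][i] - 1e-6
        fd <- (lossfun(np) - lossfun(nmn)) / 2e-6
        errs <- c(errs, abs(fd - grads[[nm]][i]) / max(abs(fd), 1e-8))
      }
    }
  })
  # a handful of parameters may sit on a ReLU/maxpool kink where finite
  # differences are invalid; the bulk must agree tightly
  expect_lt(stats::median(errs), 1e-7)
  expect_lt(stats::quantile(errs, 0.9), 1e-5)
})

test_that("training identity pairs reduces held-out error", {
  # 8 phantoms, labels equal inputs (no residual so the net must learn it)
  imgs <- lapply(1:8, function(s) make_phantom(c(32, 32), seed = s)$image)
  net <- build_unet(unet_config(base_filters = 4, residual = FALSE), seed = 2)
  r <- train_unet(net, imgs, imgs, val_idx = 7:8,
                  train_config(max_epochs = 8, batch_size = 4, seed = 1))
  expect_lt(min(r$history$val_loss), r$history$val_loss[1])
})

test_that("checkpoints round-trip through HDF5 + JSON sidecar", {
  net <- build_unet(unet_config(base_filters = 4), seed = 5)
  net$bn_state[[1]] <- net$bn_state[[1]] + 0.123   # distinguishable state
  path <- tempfile(fileext = ".h5")
  write_checkpoint(net, path)
  back <- read_checkpoint(path)
  expect_equal(back$params, net$params)
  expect_equal(back$bn_state, net$bn_state)
  expect_equal(back$config, net$config)
  k <- rand_complex(32, seed = 1)
  expect_identical(forward_knet(k, back), forward_knet(k, net))
  file.remove(path, paste0(path, ".json"))
})
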