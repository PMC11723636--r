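test_that("training sets store consistent example fields", {
  vols <- lapply(1:2, function(v) simulate_volume(c(32, 32), 4, 3, seed = v))
  ds <- make_training_set(vols, af = 2, mask_seed = 9)
  expect_length(ds$examples, 6L)
  e <- ds$examples[[4]]
  # label composite equals adaptive combine of fully sampled coil images
  mc <- volume_frame(vols[[2]], 1)
  expect_equal(e$label_img, adaptive_combine(mc$coil_images, vols[[2]]$maps))
  # acquired k-space is zero off-mask for every example
  for (ex in ds$examples) {
    off <- which(ex$acquired$mask$mask2d == 0)
    for (ci in 1:4) {
      expect_true(all(ex$acquired$coil_kspace_acq[, , ci][off] == 0))
    }
  }
  # zero-filled pairs are transforms of each other
  expect_lt(max_mod(fft2c(e$zf_img) - e$zf_k), 1e-12)
  # per-volume masks: same within a volume, different across volumes
  expect_identical(ds$examples[[1]]$acquired$mask$lines,
                   ds$examples[[2]]$acquired$mask$lines)
  expect_false(identical(ds$examples[[1]]$acquired$mask$lines,
                         ds$examples[[4]]$acquired$mask$lines))
})

test_that("with pass-through subnets both cascades reduce to MCDC chains", {
  fx <- fx_mc64()
  s <- fx_maps64()
  for (af in c(2, 4)) {
    acq <- acquire(fx$mc, vd_mask(64, af, seed = 9, nx = 64))
    zf <- zero_filled(acq, s)
    ki <- ki_reconstruct(acq, s, passthrough_cascade("KI"))
    ik <- ik_reconstruct(acq, s, passthrough_cascade("IK"))
    hand_ki <- mcdc(mcdc(ifft2c(fft2c(zf)), s, acq), s, acq)
    hand_ik <- mcdc(ifft2c(fft2c(mcdc(zf, s, acq))), s, acq)
    expect_lt(max_mod(ki - hand_ki), 1e-8)
    expect_lt(max_mod(ik - hand_ik), 1e-8)
  }
  # full sampling: both orders return the reference exactly
  acqf <- acquire(fx$mc, full_mask64())
  expect_lt(max_mod(ki_reconstruct(acqf, s, passthrough_cascade("KI")) -
                      fx$ref), 1e-8)
  expect_lt(max_mod(ik_reconstruct(acqf, s, passthrough_cascade("IK")) -
                      fx$ref), 1e-8)
  # order mismatch is rejected
  expect_error(ki_reconstruct(acqf, s, passthrough_cascade("IK")), "order")
  expect_error(ik_reconstruct(acqf, s, passthrough_cascade("KI")), "order")
})

test_that("two-stage cascade training keeps per-stage books", {
  vols <- lapply(1:3, function(v) simulate_volume(c(32, 32), 4, 4, seed = v))
  ds <- make_training_set(vols, af = 2, mask_seed = 3)
  tc <- train_config(max_epochs = 2, batch_size = 4, seed = 5)
  uc <- unet_config(base_filters = 4)
  model <- train_cascade(ds, order = "IK", tconf = tc, uconf = uc)
  expect_s3_class(model, "cascade_model")
  expect_identical(model$order, "IK")
  expect_lte(nrow(model$history1), 2L)
  expect_lte(nrow(model$history2), 2L)
  expect_true(all(is.finite(model$history1$val_loss)))
  expect_gt(model$stage2_input_val_loss, 0)
  # stage-2 inputs are reproducible from the frozen stage-1 model
  e <- ds$examples[[1]]
  i1 <- fft2c(mcdc(forward_inet(e$zf_img, model$subnet1), e$maps, e$acquired))
  i2 <- fft2c(mcdc(forward_inet(e$zf_img, model$subnet1), e$maps, e$acquired))
  expect_identical(i1, i2)
  # reconstruction runs end-to-end
  out <- ik_reconstruct(e$acquired, e$maps, model)
  expect_identical(dim(out), c(32L, 32L))
  expect_true(all(is.finite(Mod(out))))
  expect_error(train_cascade(structure(list(examples = list(), af = 2,
                                            shape = c(32L, 32L)),
                                       class = "recon_dataset"),
                             order = "IK", tconf = tc, uconf = uc),
               "empty")
})

test_that("trained cascades round-trip through their checkpoint files", {
  vols <- lapply(1:2, function(v) simulate_volume(c(32, 32), 2, 3, seed = v))
  ds <- make_training_set(vols, af = 2, mask_seed = 1)
  model <- train_cascade(ds, order = "KI",
                         tconf = train_config(max_epochs = 1, batch_size = 4,
                                              seed = 2),
                         uconf = unet_config(base_filters = 4))
  prefix <- file.path(tempdir(), "casc")
  save_cascade(model, prefix)
  back <- load_cascade(prefix)
  e <- ds$examples[[1]]
  expect_identical(ki_reconstruct(e$acquired, e$maps, back),
                   ki_reconstruct(e$acquired, e$maps, model))
  expect_identical(back$order, "KI")
  expect_equal(back$history1$val_loss, model$history1$val_loss)
})

test_that("center-calibrated Walsh maps feed the cascade at inference", {
  fx <- fx_mc64()
  acq <- acquire(fx$mc, vd_mask(64, 2, seed = 4, nx = 64))
  w <- center_calibrated_maps(acq)
  rss <- apply(abs(w$maps)^2, c(1, 2), sum)
  expect_lt(max(abs(rss - 1)), 1e-10)
  out <- ik_reconstruct(acq, w, passthrough_cascade("IK"))
  expect_true(all(is.finite(Mod(out))))
})
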