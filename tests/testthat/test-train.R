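# Controlled runs exercising the optimizer schedule: training a residual net
# on identity pairs gives zero loss from epoch 1, so the validation loss can
# never improve and both the plateau learning-rate reduction and early
# stopping must fire at their stated patience.
test_that("learning rate drops by 10x after lr_patience stale epochs", {
  imgs <- lapply(1:6, function(s) make_phantom(c(32, 32), seed = s)$image)
  net <- build_unet(unet_config(base_filters = 4, residual = TRUE, init_sd = 0),
                    seed = 1)
  tc <- train_config(max_epochs = 25, batch_size = 4, lr_patience = 10,
                     es_patience = 50, seed = 3)
  r <- train_unet(net, imgs, imgs, val_idx = 5:6, tc)
  h <- r$history
  # val loss is exactly 0 from epoch 1 (identity net, identity task), so
  # epoch 1 improves over Inf and epochs 2..11 are stale -> drop after 11
  expect_equal(h$lr[1:11], rep(1e-3, 11))
  expect_equal(h$lr[12], 1e-4)
  expect_equal(h$lr[22], 1e-5)
})

test_that("early stopping halts after es_patience stale epochs", {
  imgs <- lapply(1:6, function(s) make_phantom(c(32, 32), seed = s)$image)
  net <- build_unet(unet_config(base_filters = 4, residual = TRUE, init_sd = 0),
                    seed = 1)
  tc <- train_config(max_epochs = 100, batch_size = 4, es_patience = 20,
                     seed = 3)
  r <- train_unet(net, imgs, imgs, val_idx = 5:6, tc)
  expect_identical(nrow(r$history), 21L)   # 1 improving + 20 stale epochs
})

test_that("history bookkeeping matches the configured epoch budget", {
  imgs <- lapply(1:6, function(s) make_phantom(c(32, 32), seed = s)$image)
  labs <- lapply(1:6, function(s) make_phantom(c(32, 32), seed = s + 50)$image)
  net <- build_unet(unet_config(base_filters = 4), seed = 2)
  r <- train_unet(net, imgs, labs, val_idx = 5:6,
                  train_config(max_epochs = 2, batch_size = 4, seed = 1))
  expect_lte(nrow(r$history), 2L)
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss") %in%
                    names(r$history)))
  expect_true(all(is.finite(r$history$val_loss)))
  # the identity (input) validation loss is reported for stage comparisons
  expect_gt(r$input_val_loss, 0)
})

test_that("the learning-rate trace always follows the plateau rule", {
  # reconstructible from the recorded validation losses alone
  imgs <- lapply(1:8, function(s) make_phantom(c(32, 32), seed = s)$image)
  labs <- lapply(imgs, function(z) z * 0.9)
  net <- build_unet(unet_config(base_filters = 4), seed = 7)
  tc <- train_config(max_epochs = 18, batch_size = 4, lr_patience = 3,
                     es_patience = 50, seed = 2)
  r <- train_unet(net, imgs, labs, val_idx = 7:8, tc)
  expect_identical(r$history$lr, expected_lr_trace(r$history$val_loss,
                                                   tc$lr0, tc$lr_factor,
                                                   tc$lr_patience))
})
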