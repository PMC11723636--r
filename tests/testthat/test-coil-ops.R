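test_that("acquired_data rejects non-zero-filled k-space and shape mismatch", {
  m <- vd_mask(64, 2, seed = 1, nx = 64)
  k <- array(1 + 0i, c(64, 64, 2))
  expect_error(acquired_data(k, m), "zero at unsampled")
  expect_error(acquired_data(array(0i, c(32, 32, 2)), m), "shape mismatch")
})

test_that("Walsh estimation is exact in the single-pixel-block regime", {
  s <- fx_maps64()
  # nonvanishing magnitude so every pixel carries coil information
  img <- (Mod(fx_phantom64()$image) + 0.3) * exp(1i * 0.2)
  mc <- expand_to_coils(img, s)
  w <- walsh_maps(mc$coil_images, block_size = 1)
  expect_lt(max(abs(Mod(w$maps) - Mod(s$maps))), 1e-10)
  # complex agreement after referencing the true maps to coil 1 as well
  ph <- s$maps[, , 1] / Mod(s$maps[, , 1])
  for (ci in c(2L, 7L)) {
    expect_lt(max_mod(w$maps[, , ci] - s$maps[, , ci] * Conj(ph)), 1e-8)
  }
})

test_that("Walsh block averaging introduces the expected edge bias", {
  s <- fx_maps64()
  img <- (Mod(fx_phantom64()$image) + 0.3) * exp(1i * 0.2)
  mc <- expand_to_coils(img, s)
  w7 <- walsh_maps(mc$coil_images, block_size = 7)
  err <- abs(Mod(w7$maps) - Mod(s$maps))
  # biased near intensity edges/boundary, but small almost everywhere
  expect_lt(stats::median(err), 0.01)
  expect_lt(max(err), 0.5)
  expect_gt(max(err), 1e-3)   # the bias is real: see package vignette
})

test_that("Walsh output permutes with coil order and is unit-RSS", {
  s <- fx_maps64()
  img <- (Mod(fx_phantom64()$image) + 0.3)
  mc <- expand_to_coils(img * (1 + 0i), s)
  w <- walsh_maps(mc$coil_images, block_size = 5)
  rss <- apply(abs(w$maps)^2, c(1, 2), sum)
  expect_lt(max(abs(rss - 1)), 1e-10)
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 6L, 7L)
  wp <- walsh_maps(mc$coil_images[, , perm], block_size = 5)
  # same subspace: compare magnitudes slot by slot
  expect_equal(Mod(wp$maps), Mod(w$maps[, , perm]), tolerance = 1e-8)
  # single coil: unit magnitude
  w1 <- walsh_maps(mc$coil_images[, , 1, drop = FALSE], block_size = 7)
  expect_lt(max(abs(Mod(w1$maps) - 1)), 1e-10)
  expect_error(walsh_maps(mc$coil_images, block_size = 4), "odd")
  expect_error(walsh_maps(mc$coil_images, block_size = 99), "exceeds")
})

test_that("dc_single performs hard replacement exactly", {
  m <- vd_mask(64, 2, seed = 2, nx = 64)
  k_est <- rand_complex(64, seed = 5)
  acq <- undersample(rand_complex(64, seed = 6), m)
  out <- dc_single(k_est, acq, m)
  expect_equal(out[m$mask2d == 1], acq[m$mask2d == 1])
  expect_equal(out[m$mask2d == 0], k_est[m$mask2d == 0])
  expect_equal(dc_single(k_est, acq, full_mask64()), acq)
  expect_equal(dc_single(k_est, matrix(0i, 64, 64), empty_mask64()), k_est)
})

test_that("dc_single matches the hand-enumerated 4x4 case", {
  # 4x4 grid, sampled phase-encode lines (columns) 2 and 3, k_est = 0,
  # acquired = 1 on those lines: output has ones exactly there
  lines <- c(0L, 1L, 1L, 0L)
  m <- as_sampling_mask(lines, nx = 4)
  acq <- matrix(0i, 4, 4); acq[, 2:3] <- 1
  out <- dc_single(matrix(0i, 4, 4), acq, m)
  expected <- matrix(0i, 4, 4); expected[, 2:3] <- 1
  expect_identical(out, expected)
})

test_that("MCDC is exact under full sampling and empty masks", {
  fx <- fx_mc64()
  s <- fx_maps64()
  comp <- rand_complex(64, seed = 10)
  acq_full <- acquire(fx$mc, full_mask64())
  expect_lt(max_mod(mcdc(comp, s, acq_full) - fx$ref), 1e-10)
  acq_empty <- acquired_data(array(0i, c(64, 64, 8)), empty_mask64())
  expect_lt(max_mod(mcdc(comp, s, acq_empty) - comp), 1e-10)
  expect_error(mcdc(comp, fx_maps64(), acquired_data(array(0i, c(64, 64, 4)),
                                                     empty_mask64())),
               "mismatch")
})

test_that("MCDC contracts toward the acquired data without overshooting", {
  # One combine-and-reexpand pass is an averaged operator toward the
  # consistency set (not a projection): repeated application must shrink both
  # the iterate movement and the sampled-sample residual monotonically.
  fx <- fx_mc64()
  s <- fx_maps64()
  m <- vd_mask(64, 2, seed = 5, nx = 64)
  acq <- acquire(fx$mc, m)
  sampled <- which(m$mask2d == 1)
  res <- function(x) {
    sq <- 0
    for (ci in 1:8) {
      sq <- sq + sum(Mod((fft2c(s$maps[, , ci] * x) -
                            acq$coil_kspace_acq[, , ci])[sampled])^2)
    }
    sqrt(sq)
  }
  x <- zero_filled(acq, s)
  r_prev <- res(x)
  step_prev <- Inf
  for (k in 1:4) {
    xn <- mcdc(x, s, acq)
    expect_lt(res(xn), r_prev + 1e-12)
    expect_lt(max_mod(xn - x), step_prev)
    r_prev <- res(xn); step_prev <- max_mod(xn - x); x <- xn
  }
  # the true composite is an exact fixed point
  expect_lt(max_mod(mcdc(fx$ref, s, acq) - fx$ref), 1e-10)
})
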