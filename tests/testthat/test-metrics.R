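test_that("rmse and psnr match closed forms", {
  ones <- matrix(1, 10, 10)
  expect_identical(rmse(ones, ones), 0)
  expect_identical(rmse(matrix(0, 10, 10), ones), 1)
  # ref all ones, test = ref + 0.1 on exactly half the pixels -> sqrt(0.005)
  half <- ones + 0.1 * (matrix(seq_len(100), 10) <= 50)
  expect_equal(rmse(half, ones), sqrt(0.005))
  expect_equal(psnr(ones + 0.01, ones), 40)
  expect_equal(psnr(ones + 0.1, ones), 20)
  expect_identical(psnr(ones, ones), Inf)
  # scale invariance: both images scaled by c > 0
  a <- rand_complex(16, seed = 1); b <- rand_complex(16, seed = 2)
  expect_equal(psnr(3.7 * a, 3.7 * b), psnr(a, b))
  expect_equal(ssim(3.7 * a, 3.7 * b), ssim(a, b))
  expect_error(rmse(matrix(0, 2, 2), ones), "shape mismatch")
})

test_that("ssim matches an independent reference implementation", {
  i <- 1:64
  ref <- abs(outer(sin(i / 5), cos(i / 7))); ref <- ref / max(ref)
  test <- pmax(ref + 0.1 * sin(outer(i, i) / 13), 0)
  # frozen from a NumPy implementation of Wang-et-al SSIM (11x11 Gaussian
  # window, sigma 1.5, K1=0.01, K2=0.03, valid aggregation, L=1)
  expect_equal(ssim(test, ref), 0.8853586958121353, tolerance = 1e-9)
  sl <- Mod(make_phantom(c(64, 64), seed = 1, kind = "shepp_logan")$image)
  blur <- sl
  blur[2:63, 2:63] <- (sl[1:62, 2:63] + sl[3:64, 2:63] + sl[2:63, 1:62] +
                         sl[2:63, 3:64] + sl[2:63, 2:63]) / 5
  expect_equal(ssim(blur, sl), 0.7948772932157627, tolerance = 1e-9)
})

test_that("ssim basic properties hold", {
  x <- Mod(rand_complex(32, seed = 5))
  x <- (x - min(x)) / (max(x) - min(x))   # max(x) = max(1-x) = 1
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, 1 - x), ssim(1 - x, x))   # symmetry at equal peaks
  bin <- matrix(rep(c(0, 1), length.out = 32 * 32), 32)
  expect_lt(ssim(1 - bin, bin), 0.5)
})

test_that("evaluate aggregates per-image metrics into mean +- sd", {
  fx <- fx_mc64()
  recons <- list(fx$ref * 0.98, fx$ref)
  rep1 <- evaluate(recons[1], list(fx$ref), method = "m", af = 2)
  expect_identical(rep1$summary$sd, c(0, 0, 0))
  expect_identical(rep1$n_images, 1L)
  # duplicated image: same mean, sd 0
  rep2 <- evaluate(list(recons[[1]], recons[[1]]), list(fx$ref, fx$ref))
  expect_equal(rep2$summary$sd, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(rep2$summary$mean[1], rep1$summary$mean[1])
  # summary recomputable from per-image rows
  expect_equal(rep2$summary$mean[3], mean(rep2$per_image$rmse))
  # exact reconstructions excluded from PSNR mean with a warning
  expect_warning(rep3 <- evaluate(recons, list(fx$ref, fx$ref)), "infinite")
  expect_true(is.finite(rep3$summary$mean[2]))
  expect_error(evaluate(recons, list(fx$ref)), "lengths differ")
  # CSV/JSON serialization
  csvp <- tempfile(fileext = ".csv"); jsonp <- tempfile(fileext = ".json")
  write_report(rep1, csvp, jsonp)
  expect_identical(nrow(utils::read.csv(csvp)), 1L)
  js <- jsonlite::read_json(jsonp, simplifyVector = TRUE)
  expect_equal(js$summary$mean[1], rep1$summary$mean[1])
  file.remove(csvp, jsonp)
})
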