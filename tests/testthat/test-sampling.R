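test_that("vd_mask samples exactly round(ny/af) lines with a full center band", {
  for (ny in c(64L, 256L)) {
    for (af in c(2, 4)) {
      m <- vd_mask(ny, af, seed = 11)
      expect_identical(sum(m$lines), as.integer(round(ny / af)))
      n_center <- ceiling(ny / 16)
      band <- seq.int(floor((ny - n_center) / 2) + 1L, length.out = n_center)
      expect_true(all(m$lines[band] == 1L))
      # achieved acceleration within 1/ny of nominal
      expect_lt(abs(ny / sum(m$lines) - af), 1 / ny + 1e-12)
      # 2-D mask constant along the frequency-encode axis
      expect_true(all(apply(m$mask2d, 2, function(col) length(unique(col))) == 1L))
    }
  }
  # the 16 central lines of a 256-line grid at center_fraction 1/16
  m <- vd_mask(256, 4, center_fraction = 0.0625, seed = 2)
  expect_true(all(m$lines[121:136] == 1L))
})

test_that("vd_mask is deterministic per seed and validates its inputs", {
  expect_identical(vd_mask(128, 4, seed = 5)$lines, vd_mask(128, 4, seed = 5)$lines)
  expect_false(identical(vd_mask(128, 4, seed = 5)$lines,
                         vd_mask(128, 4, seed = 6)$lines))
  expect_error(vd_mask(64, 1), "af_nominal")
  expect_error(vd_mask(64, 100), "af_nominal")
  # center band larger than the total line budget
  expect_error(vd_mask(64, 8, center_fraction = 0.5), "infeasible")
})

test_that("sampling density decreases away from DC (Monte-Carlo tally)", {
  ny <- 64L
  tally <- numeric(ny)
  for (seed in 1:200) tally <- tally + vd_mask(ny, 4, seed = seed)$lines
  freq <- tally / 200
  d <- abs(seq_len(ny) - 33L)
  # average within |d| bins of width 8; binned frequency must not increase
  bins <- split(freq[d > 2], cut(d[d > 2], c(2, 10, 18, 26, 33)))
  mb <- vapply(bins, mean, numeric(1))
  expect_true(all(diff(mb) <= 0.005))
})

test_that("undersample zero-fills exactly and is idempotent", {
  k <- rand_complex(64, seed = 3)
  m <- vd_mask(64, 2, seed = 1, nx = 64)
  ku <- undersample(k, m)
  expect_equal(undersample(ku, m), ku)
  expect_equal(undersample(k, full_mask64()), k)
  expect_true(all(undersample(k, empty_mask64()) == 0))
  # counting for a random k (no exact zeros of its own)
  expect_identical(sum(ku == 0), 64L * (64L - sum(m$lines)))
  expect_error(undersample(rand_complex(32), m), "shape mismatch")
})

test_that("masks round-trip through the text format", {
  m <- vd_mask(128, 4, seed = 9)
  path <- tempfile(fileext = ".mask")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_identical(m2$lines, m$lines)
  expect_identical(m2$mask2d, m$mask2d)
  expect_equal(m2$af_nominal, m$af_nominal)
  expect_equal(m2$sigma, m$sigma)
  expect_error(read_mask(tempfile()), "not found")
})
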