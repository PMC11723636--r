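# Shared fixtures, built once per test file and cached.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_maps64 <- function(n_coils = 8L) {
  fx_get(paste0("maps64_", n_coils), function() {
    biot_savart_maps(coil_geometry(n_coils, nx = 64L), c(64L, 64L))
  })
}

fx_phantom64 <- function(seed = 3L) {
  fx_get(paste0("ph64_", seed), function() make_phantom(c(64L, 64L), seed))
}

# fully sampled 8-coil data for one 64x64 phantom + its composite reference
fx_mc64 <- function(seed = 3L) {
  fx_get(paste0("mc64_", seed), function() {
    mc <- expand_to_coils(fx_phantom64(seed)$image, fx_maps64())
    list(mc = mc, ref = adaptive_combine(mc$coil_images, fx_maps64()))
  })
}

full_mask64 <- function() as_sampling_mask(rep(1L, 64L), nx = 64L)
empty_mask64 <- function() as_sampling_mask(rep(0L, 64L), nx = 64L)

rand_complex <- function(n, m = n, seed = 1L) {
  withr::with_seed(seed, {
    matrix(complex(real = stats::rnorm(n * m),
                   imaginary = stats::rnorm(n * m)), n, m)
  })
}

max_mod <- function(x) max(Mod(x))
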