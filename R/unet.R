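#' Complex/channel packing
#'
#' Deep networks here operate on real tensors with two channels: channel 1 is
#' the real part and channel 2 the imaginary part of the complex array. The
#' two functions form an exact bijection.
#'
#' @param z Complex 2-D matrix.
#' @param t Real array `nx` x `ny` x 2.
#' @return `complex_to_channels()` returns the packed array;
#'   `channels_to_complex()` the complex matrix.
#' @export
complex_to_channels <- function(z) {
  stopifnot(length(dim(z)) == 2L)
  array(c(Re(z), Im(z)), dim = c(dim(z), 2L))
}

#' @rdname complex_to_channels
#' @export
channels_to_complex <- function(t) {
  d <- dim(t)
  if (length(d) != 3L || d[3] != 2L) {
    stop("expected an nx x ny x 2 channel-packed array, got dims (",
         paste(d, collapse = ", "), ")", call. = FALSE)
  }
  matrix(complex(real = t[, , 1L], imaginary = t[, , 2L]), d[1], d[2])
}

#' U-Net architecture configuration
#'
#' The customized U-Net used by both subnetworks: `n_conv3` 3x3 convolution
#' layers (each followed by ReLU then batch normalization), 2x2 max pooling
#' per encoder level, nearest-neighbour 2x upsampling (each followed by a 3x3
#' convolution that is counted in `n_conv3`), skip concatenations, and a
#' final 1x1 convolution followed by batch normalization with no activation.
#' `n_conv3` must equal `4 * depth + 2` (2 convolutions per encoder level, 2
#' in the bottleneck, 2 per decoder level). All convolutions are bias-free
#' and initialized from `Normal(0, init_sd^2)`.
#'
#' @param n_conv3 Number of 3x3 convolution layers (default 10).
#' @param base_filters Feature maps at the first level (default 64; small
#'   values such as 8 are used for desk-scale experiments).
#' @param depth Number of pooling levels (default 2).
#' @param init_sd Standard deviation of the normal weight initialization.
#' @param residual If `TRUE` (default) the network output is added to its
#'   input (global residual connection), so the network learns a correction
#'   term rather than the full mapping.
#' @param bn_momentum,bn_eps Batch-normalization running-statistics momentum
#'   and variance floor.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(n_conv3 = 10L, base_filters = 64L, depth = 2L,
                        init_sd = 0.05, residual = TRUE, bn_momentum = 0.9,
                        bn_eps = 1e-5) {
  n_conv3 <- as.integer(n_conv3); depth <- as.integer(depth)
  if (n_conv3 %% 2L != 0L || n_conv3 != 4L * depth + 2L) {
    stop("n_conv3 must be even and equal 4*depth + 2 (got n_conv3=", n_conv3,
         ", depth=", depth, ")", call. = FALSE)
  }
  structure(list(n_conv3 = n_conv3, base_filters = as.integer(base_filters),
                 depth = depth, in_channels = 2L, out_channels = 2L,
                 init_sd = init_sd, residual = isTRUE(residual),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "unet_config")
}

#' Instantiate a U-Net with randomly initialized weights
#'
#' @param config A [unet_config()].
#' @param seed Integer seed controlling the normal weight initialization.
#' @return An object of class `unet`: the op graph, parameter list, and
#'   batch-normalization running statistics.
#' @export
build_unet <- function(config = unet_config(), seed = 0L) {
  stopifnot(inherits(config, "unet_config"))
  F <- config$base_filters; depth <- config$depth
  ops <- list(); params <- list(); bn_state <- list()
  conv_id <- 0L; bn_id <- 0L
  add_conv_block <- function(cin, cout, K = 3L, relu = TRUE, gamma0 = 1) {
    conv_id <<- conv_id + 1L; bn_id <<- bn_id + 1L
    wname <- sprintf("w%02d", conv_id)
    gname <- sprintf("bn%02d", bn_id)
    params[[wname]] <<- matrix(stats::rnorm(cout * K * K * cin,
                                            sd = config$init_sd),
                               nrow = cout)
    params[[paste0(gname, "_g")]] <<- rep(gamma0, cout)
    params[[paste0(gname, "_b")]] <<- rep(0, cout)
    bn_state[[paste0(gname, "_mean")]] <<- rep(0, cout)
    bn_state[[paste0(gname, "_var")]] <<- rep(1, cout)
    ops[[length(ops) + 1L]] <<- list(type = "conv", K = K, cin = cin,
                                     cout = cout, w = wname)
    if (relu) ops[[length(ops) + 1L]] <<- list(type = "relu")
    ops[[length(ops) + 1L]] <<- list(type = "bn", bn = gname, c = cout)
  }
  widths <- F * 2^(0:depth)   # widths[l] = filters at level l (1-based)
  withr::with_seed(as.integer(seed), {
    cin <- config$in_channels
    for (l in seq_len(depth)) {            # encoder
      add_conv_block(cin, widths[l]); cin <- widths[l]
      add_conv_block(cin, widths[l])
      ops[[length(ops) + 1L]] <- list(type = "skip")
      ops[[length(ops) + 1L]] <- list(type = "pool")
    }
    add_conv_block(cin, widths[depth + 1L])          # bottleneck
    add_conv_block(widths[depth + 1L], widths[depth + 1L])
    cin <- widths[depth + 1L]
    for (l in rev(seq_len(depth))) {       # decoder
      ops[[length(ops) + 1L]] <- list(type = "up")
      add_conv_block(cin, widths[l])                 # post-upsample conv
      ops[[length(ops) + 1L]] <- list(type = "concat", c_skip = widths[l])
      add_conv_block(2L * widths[l], widths[l])
      cin <- widths[l]
    }
    # With a residual connection the final batch-norm scale starts at zero,
    # so the network is exactly the identity at initialization (the usual
    # residual-branch convention); without residual it starts at 1.
    add_conv_block(cin, config$out_channels, K = 1L, relu = FALSE,
                   gamma0 = if (config$residual) 0 else 1)
  })
  structure(list(config = config, ops = ops, params = params,
                 bn_state = bn_state, seed = as.integer(seed)),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  census <- unet_layer_census(x)
  cat(sprintf(
    "<unet> depth=%d, base_filters=%d, %d 3x3 conv + %d 1x1 conv layers, %s params, residual=%s\n",
    x$config$depth, x$config$base_filters, census$conv3, census$conv1,
    format(unet_n_params(x), big.mark = ","),
    x$config$residual))
  invisible(x)
}

#' Layer census and parameter count
#'
#' @param net A `unet`.
#' @return `unet_layer_census()`: list with counts of 3x3 and 1x1 convolution
#'   layers; `unet_n_params()`: total number of trainable parameters.
#' @export
unet_layer_census <- function(net) {
  ks <- vapply(net$ops, function(o) if (o$type == "conv") o$K else NA_integer_,
               integer(1))
  list(conv3 = sum(ks == 3L, na.rm = TRUE), conv1 = sum(ks == 1L, na.rm = TRUE))
}

#' @rdname unet_layer_census
#' @export
unet_n_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

# ---- forward / backward over the op graph -------------------------------
# Activations are R arrays [H, W, C, B]; conv/pool/up kernels view them as
# cubes [H, W, C*B].

.as_cube <- function(x) { d <- dim(x); dim(x) <- c(d[1], d[2], d[3] * d[4]); x }
.as_4d <- function(x, C, B) { d <- dim(x); dim(x) <- c(d[1], d[2], C, B); x }

.check_divisible <- function(dims, depth) {
  div <- 2L^depth
  if (any(dims[1:2] %% div != 0L)) {
    stop("spatial dims (", paste(dims[1:2], collapse = "x"),
         ") must be divisible by 2^depth = ", div, call. = FALSE)
  }
}

# Forward pass. x: [H, W, 2, B]. Returns list(y, cache) where cache holds
# per-op intermediates needed by unet_backward(); in inference mode
# (train = FALSE) batch norm uses running statistics and no cache is kept.
unet_forward <- function(net, x, train = FALSE) {
  .check_divisible(dim(x), net$config$depth)
  B <- dim(x)[4]
  x_in <- x
  skips <- list(); cache <- if (train) vector("list", length(net$ops)) else NULL
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$type == "conv") {
      if (train) cache[[i]] <- list(x = x)
      x <- .as_4d(.cpp_conv_fw(.as_cube(x), net$params[[op$w]], B, op$K),
                  op$cout, B)
    } else if (op$type == "relu") {
      mask <- x > 0
      if (train) cache[[i]] <- list(mask = mask)
      x <- x * mask
    } else if (op$type == "bn") {
      r <- .bn_forward(x, net$params[[paste0(op$bn, "_g")]],
                       net$params[[paste0(op$bn, "_b")]],
                       net$bn_state[[paste0(op$bn, "_mean")]],
                       net$bn_state[[paste0(op$bn, "_var")]],
                       eps = net$config$bn_eps, train = train)
      if (train) cache[[i]] <- r$cache
      x <- r$y
    } else if (op$type == "skip") {
      skips[[length(skips) + 1L]] <- x
    } else if (op$type == "pool") {
      r <- .cpp_pool_fw(.as_cube(x))
      C <- dim(x)[3]
      if (train) cache[[i]] <- list(idx = r$idx, H = dim(x)[1], W = dim(x)[2])
      x <- .as_4d(r$y, C, B)
    } else if (op$type == "up") {
      C <- dim(x)[3]
      x <- .as_4d(.cpp_up_fw(.as_cube(x)), C, B)
    } else if (op$type == "concat") {
      s <- skips[[length(skips)]]
      skips[[length(skips)]] <- NULL
      if (train) cache[[i]] <- list(c_main = dim(x)[3], c_skip = dim(s)[3])
      d <- dim(x)
      out <- array(0, dim = c(d[1], d[2], d[3] + dim(s)[3], B))
      out[, , seq_len(d[3]), ] <- x
      out[, , d[3] + seq_len(dim(s)[3]), ] <- s
      x <- out
    }
  }
  y <- x
  if (net$config$residual) y <- y + x_in
  list(y = y, cache = cache)
}

# Backward pass; gy has the shape of the network output. Returns the named
# gradient list (same names as net$params). With a residual connection the
# gradient w.r.t. the inner network output equals gy unchanged.
unet_backward <- function(net, cache, gy) {
  B <- dim(gy)[4]
  grads <- list()
  skip_grads <- list()
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]
    if (op$type == "conv") {
      r <- .cpp_conv_bw(.as_cube(cache[[i]]$x), net$params[[op$w]],
                        .as_cube(gy), B, op$K)
      grads[[op$w]] <- r$gw
      gy <- .as_4d(r$gx, op$cin, B)
    } else if (op$type == "relu") {
      gy <- gy * cache[[i]]$mask
    } else if (op$type == "bn") {
      r <- .bn_backward(gy, cache[[i]], net$params[[paste0(op$bn, "_g")]])
      grads[[paste0(op$bn, "_g")]] <- r$dg
      grads[[paste0(op$bn, "_b")]] <- r$db
      gy <- r$dx
    } else if (op$type == "skip") {
      gy <- gy + skip_grads[[length(skip_grads)]]
      skip_grads[[length(skip_grads)]] <- NULL
    } else if (op$type == "pool") {
      C <- dim(gy)[3]
      gy <- .as_4d(.cpp_pool_bw(.as_cube(gy), cache[[i]]$idx,
                                cache[[i]]$H, cache[[i]]$W), C, B)
    } else if (op$type == "up") {
      C <- dim(gy)[3]
      gy <- .as_4d(.cpp_up_bw(.as_cube(gy)), C, B)
    } else if (op$type == "concat") {
      cm <- cache[[i]]$c_main; cs <- cache[[i]]$c_skip
      skip_grads[[length(skip_grads) + 1L]] <-
        gy[, , cm + seq_len(cs), , drop = FALSE]
      gy <- gy[, , seq_len(cm), , drop = FALSE]
    }
  }
  grads
}

# ---- batch normalization --------------------------------------------------
# Normalizes per channel over (H, W, B). Running statistics are updated in
# place by the caller (see .bn_update_state); train mode uses batch
# statistics, inference mode the running statistics.

# Channel statistics are aggregated over (H, W, B) without permuting the
# array: x viewed as [H*W, C*B] has channel rep(1:C, B) for each column.
.bn_forward <- function(x, g, b, run_mean, run_var, eps, train) {
  d <- dim(x)
  C <- d[3]; B <- d[4]
  ch <- rep(seq_len(C), times = B)
  xm <- x; dim(xm) <- c(d[1] * d[2], C * B)
  if (train) {
    mu <- rowMeans(matrix(colMeans(xm), C, B))
    ex2 <- rowMeans(matrix(colMeans(xm^2), C, B))
    v <- pmax(ex2 - mu^2, 0)
  } else {
    mu <- run_mean; v <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- .cpp_colscale(xm, istd[ch], (-mu * istd)[ch])
  y <- .cpp_colscale(xhat, g[ch], b[ch])
  dim(y) <- d
  cache <- if (train) list(xhat = xhat, istd = istd, g_dims = d,
                           mu = mu, v = v) else NULL
  list(y = y, cache = cache)
}

.bn_backward <- function(gy, cache, g) {
  d <- cache$g_dims
  C <- d[3]; B <- d[4]; n <- d[1] * d[2] * d[4]
  ch <- rep(seq_len(C), times = B)
  gm <- gy; dim(gm) <- c(d[1] * d[2], C * B)
  dg <- rowSums(matrix(colSums(gm * cache$xhat), C, B))
  db <- rowSums(matrix(colSums(gm), C, B))
  dxhat <- .cpp_colscale(gm, g[ch], numeric(C * B))
  # dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- rowSums(matrix(colSums(dxhat), C, B))
  s2 <- rowSums(matrix(colSums(dxhat * cache$xhat), C, B))
  dxm <- .cpp_colscale2(dxhat, cache$istd[ch], cache$xhat,
                        (-s2 * cache$istd / n)[ch],
                        (-s1 * cache$istd / n)[ch])
  dim(dxm) <- d
  list(dx = dxm, dg = dg, db = db)
}

# Update running statistics from the batch statistics cached during a
# training forward pass.
.bn_update_state <- function(net, cache) {
  mom <- net$config$bn_momentum
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$type == "bn" && !is.null(cache[[i]])) {
      mn <- paste0(op$bn, "_mean"); vn <- paste0(op$bn, "_var")
      net$bn_state[[mn]] <- mom * net$bn_state[[mn]] +
        (1 - mom) * cache[[i]]$mu
      net$bn_state[[vn]] <- mom * net$bn_state[[vn]] +
        (1 - mom) * cache[[i]]$v
    }
  }
  net
}

# ---- complex-array inference wrappers -------------------------------------

#' Identity pass-through stub usable in place of a trained subnetwork
#'
#' Useful for isolating the deterministic (MCDC) part of a cascade: with
#' pass-through subnetworks a cascade reduces exactly to repeated MCDC of the
#' zero-filled input.
#'
#' @return An object of class `passthrough_net`.
#' @export
passthrough_net <- function() structure(list(), class = "passthrough_net")

#' Run a network on a complex 2-D array
#'
#' `forward_knet()` consumes and produces k-space arrays, `forward_inet()`
#' image-domain arrays; both share the same mechanics: the input is scaled to
#' unit maximum magnitude, packed into real/imaginary channels, passed
#' through the network in inference mode (batch normalization uses running
#' statistics, so repeated calls are identical), unpacked, and rescaled.
#'
#' @param k_in,img_in Complex 2-D matrix in the network's domain.
#' @param net A `unet` or [passthrough_net()].
#' @return Complex 2-D matrix of the same shape.
#' @export
forward_knet <- function(k_in, net) .forward_complex(k_in, net)

#' @rdname forward_knet
#' @export
forward_inet <- function(img_in, net) .forward_complex(img_in, net)

.forward_complex <- function(z, net) {
  if (inherits(net, "passthrough_net")) return(z)
  stopifnot(inherits(net, "unet"))
  scale <- max(Mod(z))
  if (scale == 0) scale <- 1
  x <- complex_to_channels(z / scale)
  dim(x) <- c(dim(x), 1L)
  y <- unet_forward(net, x, train = FALSE)$y
  dim(y) <- dim(y)[1:3]
  channels_to_complex(y) * scale
}
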