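#' Configuration of the valid-padding dense convolutional classifier
#'
#' The classifier is a DenseNet-style stack that uses valid padding
#' everywhere, so patchwise and fully convolutional inference agree exactly
#' (no border effects). It is composed of `n_dense_blocks` dense blocks,
#' each alternating 1x1 and 3x3 convolutions starting and ending with a 1x1
#' (so `convs_1x1_per_block = convs_3x3_per_block + 1`). Inside a block,
#' every 1x1 convolution receives the channel concatenation of the block
#' input and all preceding 3x3 outputs, center-cropped to the current
#' spatial size (valid padding shrinks tensors by 2 px per 3x3). Each block
#' except the last is followed by a transition block (1x1 convolution + 2x2
#' average pooling, stride 2, floor on odd sizes); the last block is
#' followed by a single 3x3 convolution producing class scores.
#' Batch-normalization and ReLU follow every convolution except that final
#' one, which gets a soft-max.
#'
#' Defaults mirror the full-scale model (3 blocks, four 1x1 at 64 channels
#' and three 3x3 at 32 channels per block, 279 px input patches at 0.5
#' micrometers per pixel, 2 classes); every dimension scales down so tests
#' and examples can run tiny instances.
#'
#' @param n_dense_blocks Number of dense blocks.
#' @param convs_3x3_per_block 3x3 convolutions per block; the block has one
#'   more 1x1 than 3x3.
#' @param channels_1x1,channels_3x3 Channel widths.
#' @param patch_px Training patch side, pixels.
#' @param n_classes Output classes (healthy, tumor).
#' @param in_channels Input channels (3 for RGB patches).
#' @param spacing_um Pixel spacing the network is trained at.
#' @return A `network_config`.
#' @export
network_config <- function(n_dense_blocks = 3, convs_3x3_per_block = 3,
                           channels_1x1 = 64, channels_3x3 = 32,
                           patch_px = 279, n_classes = 2, in_channels = 3,
                           spacing_um = 0.5) {
  cfg <- list(
    n_dense_blocks = as.integer(n_dense_blocks),
    convs_3x3_per_block = as.integer(convs_3x3_per_block),
    convs_1x1_per_block = as.integer(convs_3x3_per_block) + 1L,
    channels_1x1 = as.integer(channels_1x1),
    channels_3x3 = as.integer(channels_3x3),
    padding = "valid",
    patch_px = as.integer(patch_px),
    n_classes = as.integer(n_classes),
    in_channels = as.integer(in_channels),
    spacing_um = spacing_um
  )
  stopifnot(cfg$n_dense_blocks >= 1, cfg$convs_3x3_per_block >= 1,
            cfg$channels_1x1 >= 1, cfg$channels_3x3 >= 1,
            cfg$n_classes >= 2, cfg$in_channels >= 1)
  structure(cfg, class = "network_config")
}

#' Output geometry of the convolutional stack
#'
#' Pure layer-size arithmetic for the valid-padding stack: each 3x3
#' convolution shrinks the spatial size by 2, each 2x2/stride-2 average pool
#' maps `n` to `floor(n / 2)` (the last row/column of an odd input is
#' dropped), 1x1 convolutions leave sizes unchanged. Also reports the
#' effective output stride (`2^(n_dense_blocks - 1)`) and the minimum field
#' of view: the smallest input that yields a 1x1 output.
#'
#' @param input_h,input_w Input size in pixels.
#' @param config A [network_config()].
#' @return List with `h`, `w`, `stride`, `fov`.
#' @export
output_shape <- function(input_h, input_w, config) {
  fov <- network_fov(config)
  if (input_h < fov || input_w < fov) {
    stop(sprintf("input %dx%d smaller than the minimum field of view (%d)",
                 input_h, input_w, fov))
  }
  step <- function(n) {
    for (b in seq_len(config$n_dense_blocks)) {
      n <- n - 2L * config$convs_3x3_per_block
      if (b < config$n_dense_blocks) n <- n %/% 2L
    }
    n - 2L  # final 3x3
  }
  list(h = step(as.integer(input_h)), w = step(as.integer(input_w)),
       stride = 2L^(config$n_dense_blocks - 1L), fov = fov)
}

network_fov <- function(config) {
  s <- 1L + 2L  # output position + final 3x3
  for (b in seq(config$n_dense_blocks, 1L)) {
    s <- s + 2L * config$convs_3x3_per_block
    if (b > 1L) s <- 2L * s
  }
  s
}

# ---- parameter constructors -------------------------------------------------

he_conv <- function(kh, kw, cin, cout) {
  structure(list(
    W = array(stats::rnorm(kh * kw * cin * cout,
                           sd = sqrt(2 / (kh * kw * cin))),
              c(kh, kw, cin, cout)),
    b = numeric(cout)
  ), class = "conv_layer")
}

new_bn <- function(c) {
  structure(list(gamma = rep(1, c), beta = numeric(c),
                 running_mean = numeric(c), running_var = rep(1, c)),
            class = "bn_layer")
}

#' Build the network with He-initialized weights
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A `dense_network` (nested parameter list + config).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  n3 <- config$convs_3x3_per_block
  c1 <- config$channels_1x1; c3 <- config$channels_3x3
  with_seed(seed, {
    blocks <- vector("list", config$n_dense_blocks)
    cin_block <- config$in_channels
    for (b in seq_len(config$n_dense_blocks)) {
      layers <- list()
      for (j in seq_len(n3)) {
        cin_1 <- cin_block + (j - 1L) * c3
        layers[[paste0("conv1_", j)]] <- he_conv(1, 1, cin_1, c1)
        layers[[paste0("bn1_", j)]] <- new_bn(c1)
        layers[[paste0("conv3_", j)]] <- he_conv(3, 3, c1, c3)
        layers[[paste0("bn3_", j)]] <- new_bn(c3)
      }
      layers[["conv1_out"]] <- he_conv(1, 1, cin_block + n3 * c3, c1)
      layers[["bn1_out"]] <- new_bn(c1)
      blocks[[b]] <- layers
      cin_block <- c1
    }
    trans <- vector("list", max(config$n_dense_blocks - 1L, 0L))
    for (t in seq_along(trans)) {
      trans[[t]] <- list(conv = he_conv(1, 1, c1, c1), bn = new_bn(c1))
    }
    final_conv <- he_conv(3, 3, c1, config$n_classes)
    structure(list(config = config, blocks = blocks, trans = trans,
                   final_conv = final_conv),
              class = "dense_network")
  })
}

#' @export
print.dense_network <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(lapply(rapply(x[c("blocks", "trans", "final_conv")],
                                 length, how = "unlist"), identity)))
  cat(sprintf(
    "<dense_network> %d dense block(s) (%d x 1x1@%d / %d x 3x3@%d), stride %d, fov %d px\n",
    cfg$n_dense_blocks, cfg$convs_1x1_per_block, cfg$channels_1x1,
    cfg$convs_3x3_per_block, cfg$channels_3x3,
    2L^(cfg$n_dense_blocks - 1L), network_fov(cfg)))
  invisible(x)
}

# ---- forward primitives -----------------------------------------------------
# tensors are (N, H, W, C) double arrays; channel is the slowest dimension so
# c(a, b) concatenates channels and x[, r, c, , drop = FALSE] crops

conv_fwd <- function(x, layer, max_chunk = 4e6) {
  d <- dim(x)
  kh <- dim(layer$W)[1]; kw <- dim(layer$W)[2]
  cin <- dim(layer$W)[3]; cout <- dim(layer$W)[4]
  stopifnot(d[4] == cin)
  oh <- d[2] - kh + 1L; ow <- d[3] - kw + 1L
  Wm <- matrix(layer$W, kh * kw * cin, cout)
  if (kh == 1L && kw == 1L) {
    y <- matrix(x, d[1] * d[2] * d[3], cin) %*% Wm
    y <- sweep(y, 2, layer$b, `+`)
    dim(y) <- c(d[1], oh, ow, cout)
    return(y)
  }
  y <- array(0, c(d[1], oh, ow, cout))
  # chunk over output columns to bound the im2col buffer
  cols_per_chunk <- max(1L, floor(max_chunk / (d[1] * oh * kh * kw * cin)))
  c0 <- 1L
  while (c0 <= ow) {
    c1 <- min(c0 + cols_per_chunk - 1L, ow)
    nc <- c1 - c0 + 1L
    M <- matrix(0, d[1] * oh * nc, kh * kw * cin)
    blk <- 1L
    for (ci in seq_len(cin)) {
      for (dx in 0:(kw - 1L)) {
        for (dy in 0:(kh - 1L)) {
          M[, blk] <- x[, dy + seq_len(oh), dx + (c0:c1), ci]
          blk <- blk + 1L
        }
      }
    }
    # column order above is (dy, dx, ci) fastest-to-slowest, matching W's
    # (kh, kw, cin) layout
    ych <- M %*% Wm
    ych <- sweep(ych, 2, layer$b, `+`)
    y[, , c0:c1, ] <- array(ych, c(d[1], oh, nc, cout))
    c0 <- c1 + 1L
  }
  y
}

bn_fwd <- function(x, bn, training = FALSE, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  xhat <- sweep(sweep(m, 2, mu, `-`), 2, sqrt(v + eps), `/`)
  y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  dim(y) <- d
  if (training) {
    attr(y, "cache") <- list(xhat = xhat, mu = mu, v = v, eps = eps)
  }
  y
}

crop_center <- function(x, oh, ow) {
  d <- dim(x)
  mh <- (d[2] - oh) %/% 2L
  mw <- (d[3] - ow) %/% 2L
  x[, mh + seq_len(oh), mw + seq_len(ow), , drop = FALSE]
}

avgpool_fwd <- function(x) {
  d <- dim(x)
  oh <- d[2] %/% 2L; ow <- d[3] %/% 2L
  (x[, 2L * seq_len(oh) - 1L, 2L * seq_len(ow) - 1L, , drop = FALSE] +
     x[, 2L * seq_len(oh), 2L * seq_len(ow) - 1L, , drop = FALSE] +
     x[, 2L * seq_len(oh) - 1L, 2L * seq_len(ow), , drop = FALSE] +
     x[, 2L * seq_len(oh), 2L * seq_len(ow), , drop = FALSE]) / 4
}

softmax4 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# ---- full forward pass ------------------------------------------------------

block_fwd <- function(x, layers, n3, training = FALSE, cache = NULL) {
  keep <- !is.null(cache)
  feats <- list(x)   # block input followed by the 3x3 outputs
  if (keep) cache$feats_dims <- list(dim(x))
  for (j in seq_len(n3)) {
    cur <- dim(feats[[length(feats)]])[2:3]
    cropped <- lapply(feats, crop_center, oh = cur[1], ow = cur[2])
    u <- array(unlist(cropped, use.names = FALSE),
               c(dim(x)[1], cur[1], cur[2],
                 sum(vapply(cropped, function(f) dim(f)[4], numeric(1)))))
    a <- conv_fwd(u, layers[[paste0("conv1_", j)]])
    abn <- bn_fwd(a, layers[[paste0("bn1_", j)]], training)
    y <- pmax(abn, 0)
    z <- conv_fwd(y, layers[[paste0("conv3_", j)]])
    zbn <- bn_fwd(z, layers[[paste0("bn3_", j)]], training)
    zr <- pmax(zbn, 0)
    if (keep) {
      cache[[paste0("u_", j)]] <- u
      cache[[paste0("bn1c_", j)]] <- attr(abn, "cache")
      cache[[paste0("relu1_", j)]] <- abn > 0
      cache[[paste0("y_", j)]] <- y
      cache[[paste0("bn3c_", j)]] <- attr(zbn, "cache")
      cache[[paste0("relu3_", j)]] <- zbn > 0
    }
    feats[[j + 1L]] <- zr
  }
  cur <- dim(feats[[length(feats)]])[2:3]
  cropped <- lapply(feats, crop_center, oh = cur[1], ow = cur[2])
  u <- array(unlist(cropped, use.names = FALSE),
             c(dim(x)[1], cur[1], cur[2],
               sum(vapply(cropped, function(f) dim(f)[4], numeric(1)))))
  a <- conv_fwd(u, layers[["conv1_out"]])
  abn <- bn_fwd(a, layers[["bn1_out"]], training)
  out <- pmax(abn, 0)
  if (keep) {
    cache$u_out <- u
    cache$bn1c_out <- attr(abn, "cache")
    cache$relu_out <- abn > 0
    cache$feat_dims <- lapply(feats, dim)
    attr(out, "cache") <- cache
  }
  out
}

#' Forward pass of the network
#'
#' Applies the full stack to a batch of inputs. In inference mode
#' batch-normalization uses its running statistics, so the output is a
#' deterministic, translation-consistent function of the input — the
#' property that makes tiled fully convolutional inference exact.
#'
#' @param net A `dense_network`.
#' @param x Input array `(N, H, W, C)` or a single image `(H, W, C)`.
#' @param training Use batch statistics (TRUE) or running statistics.
#' @return Class-probability array `(N, OH, OW, n_classes)`; positionwise
#'   soft-max, so the class maps sum to 1 everywhere.
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  fw <- network_logits(net, x, training = training)
  softmax4(fw$logits)
}

# full forward with caches (used by both inference and backprop)
network_logits <- function(net, x, training = FALSE) {
  cfg <- net$config
  caches <- list(x = x)
  h <- x
  for (b in seq_along(net$blocks)) {
    cache_b <- if (training) list() else NULL
    h <- block_fwd(h, net$blocks[[b]], cfg$convs_3x3_per_block,
                   training = training, cache = cache_b)
    if (training) {
      caches[[paste0("block_in_", b)]] <- NULL
      caches[[paste0("block_cache_", b)]] <- attr(h, "cache")
      attr(h, "cache") <- NULL
    }
    if (b < length(net$blocks)) {
      a <- conv_fwd(h, net$trans[[b]]$conv)
      abn <- bn_fwd(a, net$trans[[b]]$bn, training)
      hr <- pmax(abn, 0)
      if (training) {
        caches[[paste0("trans_in_", b)]] <- h
        caches[[paste0("trans_bnc_", b)]] <- attr(abn, "cache")
        caches[[paste0("trans_relu_", b)]] <- abn > 0
        caches[[paste0("trans_prepool_dim_", b)]] <- dim(hr)
      }
      h <- avgpool_fwd(hr)
      if (training) caches[[paste0("trans_pooled_from_", b)]] <- hr
    }
  }
  if (training) caches$final_in <- h
  logits <- conv_fwd(h, net$final_conv)
  list(logits = logits, caches = if (training) caches)
}

#' Fully convolutional slide inference
#'
#' Applies the network across a whole raster, optionally in tiles.
#' Because every layer uses valid padding and tile origins are aligned to
#' the network's output stride, tiled and untiled inference produce
#' identical heatmaps. The result grid has spacing
#' `spacing_um * stride` and an offset placing each output pixel at the
#' center of its field of view; positions whose center pixel is not tissue
#' are set to 0 when a tissue mask is supplied.
#'
#' @param x Input raster `(H, W, C)` array (C must match the config).
#' @param net A `dense_network`.
#' @param spacing_um Spacing of the input raster; must match the network's
#'   training spacing within 0.1% (models are resolution-specific).
#' @param tile_out Output tile side (in heatmap pixels) for tiled
#'   inference; `NULL` runs a single pass.
#' @param tissue Optional logical matrix `(H, W)`; non-tissue positions are
#'   zeroed in the heatmap.
#' @param class Output class index to report (default 2, the tumor class).
#' @return A [new_heatmap()].
#' @export
predict_slide <- function(x, net, spacing_um = net$config$spacing_um,
                          tile_out = NULL, tissue = NULL, class = 2L) {
  if (abs(spacing_um - net$config$spacing_um) >
        1e-3 * net$config$spacing_um) {
    stop(sprintf("raster spacing %.4g does not match training spacing %.4g",
                 spacing_um, net$config$spacing_um))
  }
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  os <- output_shape(d[1], d[2], net$config)
  s <- os$stride; f <- os$fov
  scores <- matrix(0, os$h, os$w)
  if (is.null(tile_out)) {
    p <- network_forward(net, x)
    scores[, ] <- p[1, , , class]
  } else {
    r0 <- 1L
    while (r0 <= os$h) {
      r1 <- min(r0 + tile_out - 1L, os$h)
      c0 <- 1L
      while (c0 <= os$w) {
        c1 <- min(c0 + tile_out - 1L, os$w)
        rows <- ((r0 - 1L) * s + 1L):((r1 - 1L) * s + f)
        cols <- ((c0 - 1L) * s + 1L):((c1 - 1L) * s + f)
        tile <- x[rows, cols, , drop = FALSE]
        dim(tile) <- c(1L, dim(tile))
        p <- network_forward(net, tile)
        scores[r0:r1, c0:c1] <- p[1, , , class]
        c0 <- c1 + 1L
      }
      r0 <- r1 + 1L
    }
  }
  if (!is.null(tissue)) {
    ctr <- (f + 1L) %/% 2L
    ri <- (seq_len(os$h) - 1L) * s + ctr
    ci <- (seq_len(os$w) - 1L) * s + ctr
    scores[!tissue[ri, ci]] <- 0
  }
  new_heatmap(scores, spacing_um * s,
              offset_um = rep((f - s) / 2 * spacing_um, 2))
}
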