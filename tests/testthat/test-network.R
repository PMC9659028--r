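tiny_cfg <- function(...) {
  network_config(n_dense_blocks = 1, convs_3x3_per_block = 1,
                 channels_1x1 = 4, channels_3x3 = 3, patch_px = 5,
                 in_channels = 2, ...)
}

test_that("built networks have the specified block structure", {
  cfg <- network_config(n_dense_blocks = 3, convs_3x3_per_block = 3,
                        channels_1x1 = 8, channels_3x3 = 4, in_channels = 3)
  net <- build_network(cfg, seed = 1)
  expect_length(net$blocks, 3)
  expect_length(net$trans, 2)          # transitions after blocks 1-2 only
  expect_equal(dim(net$final_conv$W), c(3, 3, 8, 2))  # final 3x3 to classes
  # four 1x1 and three 3x3 per block, alternating, ending on a 1x1
  b <- net$blocks[[1]]
  expect_equal(sum(grepl("^conv1", names(b))), 4)
  expect_equal(sum(grepl("^conv3", names(b))), 3)
  expect_equal(dim(b$conv1_1$W)[1:2], c(1, 1))
  expect_equal(dim(b$conv3_1$W)[1:2], c(3, 3))
  # each 1x1 sees the block input plus all preceding 3x3 outputs
  expect_equal(dim(b$conv1_2$W)[3], 3 + 4)
  expect_equal(dim(b$conv1_out$W)[3], 3 + 3 * 4)
})

test_that("weight initialization is a pure function of the seed", {
  cfg <- tiny_cfg()
  expect_identical(build_network(cfg, seed = 7), build_network(cfg, seed = 7))
  expect_false(identical(build_network(cfg, seed = 7)$final_conv$W,
                         build_network(cfg, seed = 8)$final_conv$W))
})

test_that("output_shape matches the forward pass over random configurations", {
  set.seed(55)
  for (rep in 1:8) {
    cfg <- network_config(
      n_dense_blocks = sample(1:3, 1),
      convs_3x3_per_block = sample(1:3, 1),
      channels_1x1 = sample(3:6, 1), channels_3x3 = sample(2:4, 1),
      in_channels = sample(1:3, 1))
    net <- build_network(cfg, seed = rep)
    os <- output_shape(h <- sample(0:9, 1) + network_fov(cfg),
                       w <- sample(0:9, 1) + network_fov(cfg), cfg)
    x <- array(rnorm(h * w * cfg$in_channels), c(1, h, w, cfg$in_channels))
    p <- network_forward(net, x)
    expect_equal(dim(p)[2:3], c(os$h, os$w))
  }
})

test_that("the minimum field of view yields a 1x1 output and growing the
           input by one stride grows the output by one", {
  cfg <- network_config(n_dense_blocks = 2, convs_3x3_per_block = 2,
                        channels_1x1 = 4, channels_3x3 = 3, in_channels = 1)
  os <- output_shape(network_fov(cfg), network_fov(cfg), cfg)
  expect_equal(c(os$h, os$w), c(1, 1))
  net <- build_network(cfg, seed = 2)
  f <- os$fov; s <- os$stride
  x_big <- array(rnorm((f + s) * f), c(1, f + s, f, 1))
  p_big <- network_forward(net, x_big)
  expect_equal(dim(p_big)[2:3], c(2, 1))
  # shift equivariance: the two outputs equal forward passes of the two
  # stride-aligned windows
  p1 <- network_forward(net, x_big[, 1:f, , , drop = FALSE])
  p2 <- network_forward(net, x_big[, s + 1:f, , , drop = FALSE])
  expect_equal(p_big[1, 1, 1, ], p1[1, 1, 1, ])
  expect_equal(p_big[1, 2, 1, ], p2[1, 1, 1, ])
  expect_error(output_shape(f - 1, f, cfg), "field of view")
})

test_that("soft-max class maps sum to one everywhere", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 4)
  x <- array(rnorm(1 * 12 * 15 * 2), c(1, 12, 15, 2))
  p <- network_forward(net, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(apply(p, c(1, 2, 3), sum),
               array(1, dim(p)[1:3]), tolerance = 1e-12)
})

test_that("a constant input produces a constant heatmap", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 5)
  x <- array(0, c(20, 23, 2))
  hm <- predict_slide(x, net, spacing_um = cfg$spacing_um)
  expect_lt(diff(range(hm$scores)), 1e-12)
})

test_that("tiled and untiled inference agree exactly", {
  cfg <- network_config(n_dense_blocks = 2, convs_3x3_per_block = 1,
                        channels_1x1 = 4, channels_3x3 = 3, in_channels = 1)
  net <- build_network(cfg, seed = 6)
  set.seed(6)
  x <- array(runif(150 * 163), c(150, 163, 1))
  h_full <- predict_slide(x, net)
  for (tile in c(7, 16)) {
    h_tiled <- predict_slide(x, net, tile_out = tile)
    # agreement to floating-point summation order
    expect_lt(max(abs(h_tiled$scores - h_full$scores)), 1e-12)
  }
  expect_equal(h_full$spacing_um, cfg$spacing_um * 2)
})

test_that("heatmap grid geometry reflects stride and field of view", {
  cfg <- tiny_cfg()  # single block: stride 1
  net <- build_network(cfg, seed = 3)
  x <- array(runif(20 * 20 * 2), c(20, 20, 2))
  hm <- predict_slide(x, net)
  os <- output_shape(20, 20, cfg)
  expect_equal(dim(hm$scores), c(os$h, os$w))
  expect_equal(hm$spacing_um, cfg$spacing_um * os$stride)
  expect_equal(hm$offset_um[1], (os$fov - os$stride) / 2 * cfg$spacing_um)
  expect_error(predict_slide(x, net, spacing_um = 0.25), "spacing")
})

test_that("non-tissue positions are zeroed in the heatmap", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 9)
  x <- array(runif(20 * 20 * 2), c(20, 20, 2))
  tissue <- matrix(FALSE, 20, 20)
  tissue[1:10, ] <- TRUE
  hm <- predict_slide(x, net, tissue = tissue)
  # stride 1, fov 5: heatmap row i has center pixel row i + 2
  expect_true(all(hm$scores[9:nrow(hm$scores), ] == 0))
  expect_true(all(hm$scores[1:8, ] > 0))
})
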