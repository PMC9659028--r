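slides6 <- c(toy_slides(1, 2, dataset = "Loc", seed = 3),
             toy_slides(1, 2, dataset = "Cam", seed = 4))

test_that("the epoch sampler hits the 20/80 tumor fraction within 3 sigma", {
  cfg <- train_config(patches_per_epoch = 5000, patch_px = 9, seed = 5)
  co <- sample_epoch(slides6, cfg)
  n_tumor <- sum(co$label == "tumor")
  expect_lt(abs(n_tumor - 1000), 3 * sqrt(5000 * 0.2 * 0.8))
  expect_true(all(co$mask_code[co$label == "tumor"] == 2L))
  expect_true(all(co$mask_code[co$label == "healthy"] %in% c(1L, 3L)))
  # reproducible given the seed
  expect_identical(co, sample_epoch(slides6, cfg))
  expect_false(identical(co, sample_epoch(slides6, cfg, epoch = 2L)))
})

test_that("local upweighting scales per-source draws by the factor", {
  cfg <- train_config(patches_per_epoch = 8000, patch_px = 9, seed = 6)
  st <- strategy_config(sampling_mode = "local_upweighted",
                        local_upweight_factor = 4,
                        local_datasets = "Loc")
  co <- sample_epoch(slides6, cfg, st)
  masks <- lapply(slides6, function(sl) {
    label_mask(sl$annotations, sl$raster$tissue, 16)
  })
  hp <- vapply(masks, function(m) sum(m == 1L), numeric(1))
  is_loc <- vapply(slides6, function(sl) sl$record$dataset == "Loc",
                   logical(1))
  expected_ratio <- 4 * sum(hp[is_loc]) / sum(hp[!is_loc])
  tt <- table(co$dataset[co$label == "healthy"])
  got_ratio <- tt[["Loc"]] / tt[["Cam"]]
  n <- sum(tt)
  p <- expected_ratio / (1 + expected_ratio)
  expect_lt(abs(tt[["Loc"]] - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("hard-negative weighting oversamples code-3 pixels", {
  sl <- slides6[[2]]
  mask <- label_mask(sl$annotations, sl$raster$tissue, 16)
  healthy <- which(mask == 1L)
  mask[healthy[seq_len(floor(length(healthy) / 10))]] <- 3L  # 10% mined
  cfg <- train_config(patches_per_epoch = 6000, patch_px = 9,
                      tumor_fraction = 0, seed = 7)
  st <- strategy_config(hnm_enabled = TRUE, hnm_code_sampling_weight = 8)
  co <- sample_epoch(list(sl), cfg, st, masks = list(mask))
  frac3 <- mean(co$mask_code == 3L)
  n1 <- sum(mask == 1L); n3 <- sum(mask == 3L)
  p <- 8 * n3 / (8 * n3 + n1)
  expect_lt(abs(frac3 - p), 3 * sqrt(p * (1 - p) / 6000))
})

test_that("mining with no code-3 pixels is identical to mining disabled", {
  cfg <- train_config(patches_per_epoch = 500, patch_px = 9, seed = 8)
  on <- sample_epoch(slides6, cfg,
                     strategy_config(hnm_enabled = TRUE,
                                     hnm_code_sampling_weight = 10))
  off <- sample_epoch(slides6, cfg, strategy_config())
  expect_identical(on, off)
})

test_that("augmentation preserves dimensions, range, and composes correctly", {
  set.seed(9)
  p <- array(runif(11 * 11 * 3), c(11, 11, 3))
  id <- list(flip = FALSE, rot = 0, scale = 1, hue = 0, saturation = 0,
             brightness = 0, contrast = 0, noise_sd = 0, blur_sigma = 0)
  expect_equal(augment(p, params = id), p, ignore_attr = TRUE)
  r <- p
  for (i in 1:4) r <- augment(r, params = modifyList(id, list(rot = 90)))
  expect_equal(r, p, ignore_attr = TRUE)
  f2 <- augment(augment(p, params = modifyList(id, list(flip = TRUE))),
                params = modifyList(id, list(flip = TRUE)))
  expect_equal(f2, p, ignore_attr = TRUE)
  a1 <- augment(p, seed = 42)
  expect_identical(a1, augment(p, seed = 42))
  expect_equal(dim(a1), dim(p))
  expect_true(min(a1) >= 0 && max(a1) <= 1)
  expect_named(attr(a1, "params"),
               c("flip", "rot", "scale", "hue", "saturation", "brightness",
                 "contrast", "noise_sd", "blur_sigma"))
  # parameter draws stay inside the stated ranges
  draws <- lapply(1:50, function(s) attr(augment(p, seed = s), "params"))
  expect_true(all(vapply(draws, function(d) d$scale, 1) >= 0.9))
  expect_true(all(vapply(draws, function(d) d$scale, 1) <= 1.1))
  expect_true(all(abs(vapply(draws, function(d) d$hue, 1)) <= 0.1))
  expect_true(all(vapply(draws, function(d) d$noise_sd, 1) <= 0.05))
  expect_true(all(vapply(draws, function(d) d$rot, 1) %in%
                    c(0, 90, 180, 270)))
})

test_that("brightness and contrast act additively/multiplicatively in RGB", {
  p <- array(0.4, c(5, 5, 3))
  id <- list(flip = FALSE, rot = 0, scale = 1, hue = 0, saturation = 0,
             brightness = 0.1, contrast = 0, noise_sd = 0, blur_sigma = 0)
  expect_equal(unique(as.vector(augment(p, params = id))), 0.5)
  id$brightness <- 0; id$contrast <- 0.25
  expect_equal(unique(as.vector(augment(p, params = id))), 0.5)
})

test_that("the schedule drops the rate on plateaus and stops early", {
  # strictly improving: rate never drops, runs to the cap
  h <- lr_schedule(seq(0.5, 0.9, length.out = 30), lr_init = 1e-4,
                   max_epochs = 30)
  expect_equal(nrow(h), 30)
  expect_true(all(h$lr == 1e-4))
  expect_false(any(h$stopped[-30]))
  # constant from epoch 1: stop at 1 + patience
  h2 <- lr_schedule(rep(0.7, 100), early_stop_patience = 20)
  expect_equal(nrow(h2), 21)
  expect_true(h2$stopped[21])
  # a 4-epoch plateau drops the rate going into the next epoch
  acc <- c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7)
  h3 <- lr_schedule(acc, lr_init = 1e-3, lr_patience = 4)
  expect_equal(h3$lr[6], 1e-3)   # epochs 3-6 without gain trigger the drop
  expect_equal(h3$lr[7], 1e-4)   # ... applied from epoch 7
  expect_equal(h3$lr[11], 1e-4)  # epoch-7 best resets the plateau counter
  expect_equal(h3$lr[12], 1e-5)  # epochs 8-11 without gain drop again
  expect_equal(h3$best_so_far[12], 0.7)
})

test_that("a separable patch set trains to perfect accuracy", {
  cfg <- network_config(n_dense_blocks = 1, convs_3x3_per_block = 1,
                        channels_1x1 = 6, channels_3x3 = 4, patch_px = 5,
                        in_channels = 3)
  net <- build_network(cfg, seed = 1)
  set.seed(10)
  n <- 40
  y <- rep(1:2, length.out = n)
  x <- array(rnorm(n * 5 * 5 * 3, 0.5, 0.08), c(n, 5, 5, 3))
  x[y == 2, , , 1] <- x[y == 2, , , 1] - 0.2
  stream <- function(epoch) list(x = x, y = y)
  tc <- train_config(patches_per_epoch = n, patch_px = 5, max_epochs = 12,
                     lr_init = 5e-3, batch_size = 20, augment = FALSE,
                     seed = 2, lr_patience_epochs = 4,
                     early_stop_patience = 10)
  out <- train_network(net, stream, stream, tc)
  expect_gte(max(out$history$train_acc), 0.95)
  expect_equal(names(out$history),
               c("epoch", "lr", "train_loss", "train_acc", "val_acc"))
})

test_that("strategy dispatch honors transfer modes", {
  cfg <- network_config(n_dense_blocks = 1, convs_3x3_per_block = 1,
                        channels_1x1 = 4, channels_3x3 = 3, patch_px = 5,
                        in_channels = 3)
  tc <- train_config(patches_per_epoch = 32, patch_px = 5, max_epochs = 2,
                     batch_size = 16, augment = FALSE, seed = 3,
                     lr_patience_epochs = 1, early_stop_patience = 1)
  expect_error(
    run_strategy(NULL, slides6, slides6[1:2],
                 strategy_config(transfer_mode = "finetune_local",
                                 local_datasets = "Loc"), tc),
    "base checkpoint")
  base <- build_network(cfg, seed = 4)
  out <- run_strategy(base, slides6, slides6[1:2],
                      strategy_config(transfer_mode = "finetune_local",
                                      local_datasets = "Loc"),
                      tc)
  expect_s3_class(out$net, "dense_network")
  expect_error(
    run_strategy(base, slides6, slides6[1:2],
                 strategy_config(transfer_mode = "finetune_local",
                                 local_datasets = "Nowhere"), tc),
    "no slides")
})
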