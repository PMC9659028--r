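#' Training configuration
#'
#' Bundles the optimization schedule used throughout the study: categorical
#' cross-entropy with L2 weight decay (1e-4) minimized by Adam from an
#' initial learning rate of 1e-4; the rate drops by a factor of 10 after 4
#' epochs without validation-accuracy improvement; training stops early
#' after 20 epochs without improvement, capped at 200 epochs. Each epoch
#' samples `patches_per_epoch` patches (full-scale default 262,144) with a
#' 20/80 tumor/healthy ratio at 279 px.
#'
#' @param patches_per_epoch Patches sampled per epoch for the training and
#'   validation sets individually; scale down for desk-size runs.
#' @param tumor_fraction Probability a sampled patch is tumor-centered.
#' @param patch_px Patch side, pixels.
#' @param l2_weight L2 penalty weight.
#' @param lr_init,lr_drop_factor,lr_patience_epochs Schedule parameters.
#' @param early_stop_patience,max_epochs Stopping parameters.
#' @param batch_size Minibatch size.
#' @param augment Apply the augmentation stack to training patches?
#' @param seed Integer seed governing sampling and shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(patches_per_epoch = 262144, tumor_fraction = 0.20,
                         patch_px = 279, l2_weight = 1e-4, lr_init = 1e-4,
                         lr_drop_factor = 10, lr_patience_epochs = 4,
                         early_stop_patience = 20, max_epochs = 200,
                         batch_size = 32, augment = TRUE, seed = 1L) {
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1,
            lr_patience_epochs < max_epochs,
            early_stop_patience < max_epochs)
  structure(list(
    loss = "categorical_crossentropy", optimizer = "adam",
    patches_per_epoch = as.integer(patches_per_epoch),
    tumor_fraction = tumor_fraction, patch_px = as.integer(patch_px),
    l2_weight = l2_weight, lr_init = lr_init,
    lr_drop_factor = lr_drop_factor,
    lr_patience_epochs = as.integer(lr_patience_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size),
    augment = augment, seed = as.integer(seed)
  ), class = "train_config")
}

#' Retraining strategy configuration
#'
#' The three strategies explored for adapting the base detector to a new
#' clinical site: (1) transfer mode — retrain from scratch on pooled data
#' versus fine-tune the base checkpoint on local data only; (2) sampling
#' mode — uniform patch sampling versus upweighting patches from the local
#' datasets; (3) hard negative mining — preferential sampling of healthy
#' patches from mask code 3 (regions a previous model flagged as false
#' positives).
#'
#' @param transfer_mode `"scratch_pooled"` or `"finetune_local"`.
#' @param sampling_mode `"uniform"` or `"local_upweighted"`.
#' @param local_upweight_factor Per-pixel sampling weight multiplier for
#'   local-dataset slides (>= 1).
#' @param hnm_enabled Enable hard-negative oversampling.
#' @param hnm_code_sampling_weight Weight multiplier for code-3 pixels when
#'   sampling healthy patches.
#' @param local_datasets Dataset names counted as "local".
#' @return A `strategy_config`.
#' @export
strategy_config <- function(transfer_mode = c("scratch_pooled",
                                              "finetune_local"),
                            sampling_mode = c("uniform", "local_upweighted"),
                            local_upweight_factor = 1,
                            hnm_enabled = FALSE,
                            hnm_code_sampling_weight = 1,
                            local_datasets = character()) {
  transfer_mode <- match.arg(transfer_mode)
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(local_upweight_factor >= 1, hnm_code_sampling_weight >= 1)
  structure(list(transfer_mode = transfer_mode,
                 sampling_mode = sampling_mode,
                 local_upweight_factor = local_upweight_factor,
                 hnm_enabled = hnm_enabled,
                 hnm_code_sampling_weight = hnm_code_sampling_weight,
                 local_datasets = local_datasets),
            class = "strategy_config")
}

#' Sample one epoch of patch coordinates
#'
#' Draws `n_patches` patch centers from the slides' label masks. The class
#' is drawn first (tumor with probability `tumor_fraction`), then a pixel of
#' that class with probability proportional to its sampling weight: local
#' slides' pixels are multiplied by `local_upweight_factor` under
#' `local_upweighted` sampling, and code-3 (hard negative) pixels by
#' `hnm_code_sampling_weight` when mining is enabled. Tumor patches come
#' from code-2 pixels, healthy patches from codes 1 and 3.
#'
#' @param slides List of slides from [generate_slide()].
#' @param config A [train_config()].
#' @param strategy A [strategy_config()].
#' @param n_patches Number of patches (defaults to
#'   `config$patches_per_epoch`).
#' @param masks Optional precomputed label masks (list of integer
#'   matrices); computed from annotations otherwise.
#' @param epoch Epoch index mixed into the sampling seed.
#' @return Tibble: `slide`, `slide_id`, `dataset`, `label`
#'   (`"tumor"`/`"healthy"`), `row`, `col` (mask pixel), `mask_code`.
#' @export
sample_epoch <- function(slides, config, strategy = strategy_config(),
                         n_patches = config$patches_per_epoch, masks = NULL,
                         epoch = 1L) {
  if (is.null(masks)) {
    masks <- lapply(slides, function(sl) {
      label_mask(sl$annotations, sl$raster$tissue, sl$raster$spacing_um)
    })
  }
  is_local <- vapply(slides, function(sl) {
    sl$record$dataset %in% strategy$local_datasets
  }, logical(1))
  slide_mult <- ifelse(is_local & strategy$sampling_mode == "local_upweighted",
                       strategy$local_upweight_factor, 1)
  hnm_w <- if (strategy$hnm_enabled) strategy$hnm_code_sampling_weight else 1

  pools <- list(
    tumor = lapply(masks, function(m) which(m == 2L)),
    healthy = lapply(masks, function(m) which(m == 1L | m == 3L))
  )
  # per-slide total sampling weight per class
  wt <- list(
    tumor = vapply(seq_along(slides), function(s) {
      length(pools$tumor[[s]]) * slide_mult[s]
    }, numeric(1)),
    healthy = vapply(seq_along(slides), function(s) {
      idx <- pools$healthy[[s]]
      if (!length(idx)) return(0)
      (sum(masks[[s]][idx] == 1L) + hnm_w * sum(masks[[s]][idx] == 3L)) *
        slide_mult[s]
    }, numeric(1))
  )
  if (config$tumor_fraction > 0 && sum(wt$tumor) == 0) {
    stop("no tumor pixels available but tumor_fraction > 0")
  }
  if (config$tumor_fraction < 1 && sum(wt$healthy) == 0) {
    stop("no healthy pixels available")
  }
  with_seed(derive_seed(config$seed, 101L, epoch), {
    lab <- ifelse(stats::runif(n_patches) < config$tumor_fraction,
                  "tumor", "healthy")
    out <- vector("list", 2L)
    for (cls in c("tumor", "healthy")) {
      n_cls <- sum(lab == cls)
      if (n_cls == 0L) next
      s_draw <- sample.int(length(slides), n_cls, replace = TRUE,
                           prob = wt[[cls]])
      px <- integer(n_cls); code <- integer(n_cls)
      for (s in unique(s_draw)) {
        sel <- which(s_draw == s)
        idx <- pools[[cls]][[s]]
        pw <- NULL
        if (cls == "healthy" && hnm_w != 1) {
          codes <- masks[[s]][idx]
          # weights only when code-3 pixels exist, so mining with no mined
          # regions is draw-for-draw identical to mining disabled
          if (any(codes == 3L)) pw <- ifelse(codes == 3L, hnm_w, 1)
        }
        take <- idx[sample.int(length(idx), length(sel), replace = TRUE,
                               prob = pw)]
        px[sel] <- take
        code[sel] <- masks[[s]][take]
      }
      h <- vapply(s_draw, function(s) nrow(masks[[s]]), integer(1))
      out[[cls]] <- tibble::tibble(
        slide = s_draw,
        slide_id = vapply(s_draw, function(s) slides[[s]]$record$slide_id,
                          character(1)),
        dataset = vapply(s_draw, function(s) slides[[s]]$record$dataset,
                         character(1)),
        label = cls,
        row = ((px - 1L) %% h) + 1L,
        col = ((px - 1L) %/% h) + 1L,
        mask_code = code
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Materialize sampled patch coordinates into pixel arrays
#'
#' @param slides List of slides.
#' @param coords Tibble from [sample_epoch()].
#' @param config A [train_config()] (patch size, augmentation, seed).
#' @param masks Optional precomputed label masks.
#' @param epoch Epoch index (augmentation seed stream).
#' @return List with `x` array `(n, patch_px, patch_px, 3)` and `y` integer
#'   labels (1 = healthy, 2 = tumor).
#' @export
materialize_patches <- function(slides, coords, config, masks = NULL,
                                epoch = 1L) {
  if (is.null(masks)) {
    masks <- lapply(slides, function(sl) {
      label_mask(sl$annotations, sl$raster$tissue, sl$raster$spacing_um)
    })
  }
  n <- nrow(coords)
  x <- array(0, c(n, config$patch_px, config$patch_px, 3))
  with_seed(derive_seed(config$seed, 211L, epoch), {
    for (i in seq_len(n)) {
      s <- coords$slide[i]
      p <- render_patch(slides[[s]]$raster, masks[[s]], coords$row[i],
                        coords$col[i], config$patch_px,
                        pixel_spacing_um = slides[[s]]$record$spacing_um)
      if (config$augment) {
        p <- augment(p, seed = sample.int(2^30, 1))
      }
      x[i, , , ] <- p
    }
  })
  list(x = x, y = ifelse(coords$label == "tumor", 2L, 1L))
}

#' Stain-style patch augmentation
#'
#' Applies, in this fixed order: horizontal flip; rotation by 0/90/180/270
#' degrees; isotropic scaling in \[0.9, 1.1\] (bilinear, then center
#' crop/edge-pad back to the original size); hue offset in \[-0.1, 0.1\] and
#' saturation offset in \[-0.25, 0.25\] (HSV space, fractional units);
#' additive brightness in \[-0.25, 0.25\] and multiplicative contrast in
#' \[-0.25, 0.25\] (RGB); Gaussian noise with sd in \[0, 0.05\]; Gaussian
#' blur with sigma in \[0, 1\] pixels. Parameters are drawn uniformly from
#' these ranges, the output is clipped to \[0, 1\], and the label (not part
#' of the patch) is untouched. The draw is returned in attribute
#' `"params"` for logging; passing `params` explicitly reproduces or pins a
#' transform (all-identity parameters return the input exactly).
#'
#' @param patch `(H, W, 3)` array in `[0, 1]`.
#' @param params Optional named list: `flip` (logical), `rot` (0, 90, 180,
#'   270), `scale`, `hue`, `saturation`, `brightness`, `contrast`,
#'   `noise_sd`, `blur_sigma`.
#' @param seed Integer seed for the parameter draw.
#' @return Augmented patch with attribute `"params"`.
#' @export
augment <- function(patch, params = NULL, seed = 1L) {
  stopifnot(length(dim(patch)) == 3L, min(patch) >= 0, max(patch) <= 1)
  with_seed(seed, {
    if (is.null(params)) {
      params <- list(
        flip = stats::runif(1) < 0.5,
        rot = sample(c(0, 90, 180, 270), 1),
        scale = stats::runif(1, 0.9, 1.1),
        hue = stats::runif(1, -0.1, 0.1),
        saturation = stats::runif(1, -0.25, 0.25),
        brightness = stats::runif(1, -0.25, 0.25),
        contrast = stats::runif(1, -0.25, 0.25),
        noise_sd = stats::runif(1, 0, 0.05),
        blur_sigma = stats::runif(1, 0, 1)
      )
    }
    x <- patch
    if (isTRUE(params$flip)) x <- x[, dim(x)[2]:1, , drop = FALSE]
    k <- (params$rot %/% 90) %% 4
    if (k > 0) for (i in seq_len(k)) x <- rot90_ccw(x)
    if (params$scale != 1) x <- rescale_center(x, params$scale)
    if (params$hue != 0 || params$saturation != 0) {
      x <- adjust_hsv(x, params$hue, params$saturation)
    }
    if (params$brightness != 0) x <- x + params$brightness
    if (params$contrast != 0) x <- x * (1 + params$contrast)
    if (params$noise_sd > 0) {
      x <- x + array(stats::rnorm(length(x), 0, params$noise_sd), dim(x))
    }
    if (params$blur_sigma > 0.05) x <- gaussian_blur(x, params$blur_sigma)
    x <- pmin(pmax(x, 0), 1)
    attr(x, "params") <- params
    x
  })
}

rot90_ccw <- function(x) {
  # counter-clockwise 90-degree rotation, per channel
  d <- dim(x)
  y <- array(0, c(d[2], d[1], d[3]))
  for (c in seq_len(d[3])) y[, , c] <- t(x[, , c])[d[2]:1, , drop = FALSE]
  y
}

bilinear_resize <- function(x, oh, ow) {
  d <- dim(x)
  ry <- (seq_len(oh) - 0.5) * d[1] / oh + 0.5
  rx <- (seq_len(ow) - 0.5) * d[2] / ow + 0.5
  y0 <- pmin(pmax(floor(ry), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(rx), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  out <- array(0, c(oh, ow, d[3]))
  for (c in seq_len(d[3])) {
    ch <- x[, , c]
    out[, , c] <-
      outer(1 - wy, 1 - wx) * ch[y0, x0] + outer(1 - wy, wx) * ch[y0, x1] +
      outer(wy, 1 - wx) * ch[y1, x0] + outer(wy, wx) * ch[y1, x1]
  }
  out
}

rescale_center <- function(x, scale) {
  d <- dim(x)
  oh <- max(1L, round(d[1] * scale)); ow <- max(1L, round(d[2] * scale))
  y <- bilinear_resize(x, oh, ow)
  if (oh >= d[1]) {
    r0 <- (oh - d[1]) %/% 2L; c0 <- (ow - d[2]) %/% 2L
    y[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]
  } else {
    # edge-replicating pad back to size
    ri <- pmin(pmax(seq_len(d[1]) - (d[1] - oh) %/% 2L, 1L), oh)
    ci <- pmin(pmax(seq_len(d[2]) - (d[2] - ow) %/% 2L, 1L), ow)
    y[ri, ci, , drop = FALSE]
  }
}

adjust_hsv <- function(x, dh, ds) {
  r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  i_r <- nz & mx == r; i_g <- nz & mx == g & !i_r
  i_b <- nz & !i_r & !i_g
  h[i_r] <- (((g - b)[i_r] / delta[i_r]) %% 6) / 6
  h[i_g] <- (((b - r)[i_g] / delta[i_g]) + 2) / 6
  h[i_b] <- (((r - g)[i_b] / delta[i_b]) + 4) / 6
  s <- ifelse(mx > 0, delta / mx, 0)
  v <- mx
  h <- (h + dh) %% 1
  s <- pmin(pmax(s + ds, 0), 1)
  # HSV back to RGB
  hh <- h * 6
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r2 <- v; g2 <- t; b2 <- p
  r2[i == 1] <- q[i == 1]; g2[i == 1] <- v[i == 1]; b2[i == 1] <- p[i == 1]
  r2[i == 2] <- p[i == 2]; g2[i == 2] <- v[i == 2]; b2[i == 2] <- t[i == 2]
  r2[i == 3] <- p[i == 3]; g2[i == 3] <- q[i == 3]; b2[i == 3] <- v[i == 3]
  r2[i == 4] <- t[i == 4]; g2[i == 4] <- p[i == 4]; b2[i == 4] <- v[i == 4]
  r2[i == 5] <- v[i == 5]; g2[i == 5] <- p[i == 5]; b2[i == 5] <- q[i == 5]
  out <- x
  out[, , 1] <- r2; out[, , 2] <- g2; out[, , 3] <- b2
  out
}

gaussian_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(x)
  pad_idx <- function(n) pmin(pmax(seq(1L - r, n + r), 1L), n)
  for (c in seq_len(d[3])) {
    ch <- x[pad_idx(d[1]), pad_idx(d[2]), c]
    ch <- apply(ch, 2, function(col) stats::filter(col, k, sides = 2))
    ch <- t(apply(ch, 1, function(row) stats::filter(row, k, sides = 2)))
    x[, , c] <- ch[r + seq_len(d[1]), r + seq_len(d[2])]
  }
  x
}

#' Run a full retraining strategy
#'
#' Dispatches the transfer mode — `scratch_pooled` re-initializes the
#' network and trains on all supplied slides; `finetune_local` starts from
#' the base checkpoint and trains on the local datasets only — and composes
#' the sampling mode and hard-negative mining into the per-epoch patch
#' sampler.
#'
#' @param base_net A trained `dense_network` checkpoint, or `NULL`
#'   (required for `finetune_local`).
#' @param slides List of training slides.
#' @param val_slides List of validation slides.
#' @param strategy A [strategy_config()].
#' @param config A [train_config()].
#' @param net_config A [network_config()] used when training from scratch.
#' @param masks,val_masks Optional precomputed label masks (e.g. after
#'   hard-negative mining).
#' @return As [train_network()]: `net` and `history`.
#' @export
run_strategy <- function(base_net = NULL, slides, val_slides, strategy,
                         config, net_config = NULL, masks = NULL,
                         val_masks = NULL) {
  if (strategy$transfer_mode == "finetune_local") {
    if (is.null(base_net)) stop("finetune_local requires a base checkpoint")
    net <- base_net
    keep <- vapply(slides, function(sl) {
      sl$record$dataset %in% strategy$local_datasets
    }, logical(1))
    if (!any(keep)) stop("no slides from the local datasets to fine-tune on")
    slides <- slides[keep]
    if (!is.null(masks)) masks <- masks[keep]
  } else {
    if (is.null(net_config)) {
      net_config <- if (!is.null(base_net)) base_net$config else
        network_config()
    }
    net <- build_network(net_config, seed = derive_seed(config$seed, 77L))
  }
  train_stream <- function(epoch) {
    co <- sample_epoch(slides, config, strategy, masks = masks,
                       epoch = epoch)
    materialize_patches(slides, co, config, masks = masks, epoch = epoch)
  }
  # validation patches use a fixed per-epoch seed sequence and uniform
  # sampling, so accuracy is comparable across epochs and strategies
  val_cfg <- config
  val_cfg$augment <- FALSE
  val_cfg$seed <- derive_seed(config$seed, 999L)
  val_stream <- function(epoch) {
    co <- sample_epoch(val_slides, val_cfg, strategy_config(),
                       epoch = epoch, masks = val_masks)
    materialize_patches(val_slides, co, val_cfg, masks = val_masks,
                        epoch = epoch)
  }
  train_network(net, train_stream, val_stream, config)
}
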