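# Backpropagation for the valid-padding dense network.
#
# Gradients are accumulated into a flat environment keyed by parameter path
# ("blocks.2.conv3_1.W", "trans.1.bn.gamma", "final_conv.b", ...); the same
# keys address the Adam state. Tensors are (N, H, W, C).

conv_bwd <- function(x, layer, dy, G = NULL, key = NULL) {
  d <- dim(x); kh <- dim(layer$W)[1]; kw <- dim(layer$W)[2]
  cin <- dim(layer$W)[3]; cout <- dim(layer$W)[4]
  od <- dim(dy)
  Wm <- matrix(layer$W, kh * kw * cin, cout)
  dym <- matrix(dy, prod(od[1:3]), cout)
  if (kh == 1L && kw == 1L) {
    xm <- matrix(x, prod(d[1:3]), cin)
    dW <- crossprod(xm, dym)
    dx <- dym %*% t(Wm)
    dim(dx) <- d
  } else {
    oh <- od[2]; ow <- od[3]
    M <- matrix(0, prod(od[1:3]), kh * kw * cin)
    blk <- 1L
    for (ci in seq_len(cin)) {
      for (dxo in 0:(kw - 1L)) {
        for (dyo in 0:(kh - 1L)) {
          M[, blk] <- x[, dyo + seq_len(oh), dxo + seq_len(ow), ci]
          blk <- blk + 1L
        }
      }
    }
    dW <- crossprod(M, dym)
    Gm <- dym %*% t(Wm)
    dx <- array(0, d)
    blk <- 1L
    for (ci in seq_len(cin)) {
      for (dxo in 0:(kw - 1L)) {
        for (dyo in 0:(kh - 1L)) {
          dx[, dyo + seq_len(oh), dxo + seq_len(ow), ci] <-
            dx[, dyo + seq_len(oh), dxo + seq_len(ow), ci] +
            array(Gm[, blk], c(od[1], oh, ow))
          blk <- blk + 1L
        }
      }
    }
  }
  if (!is.null(G)) {
    G[[paste0(key, ".W")]] <- array(dW, dim(layer$W))
    G[[paste0(key, ".b")]] <- colSums(dym)
  }
  dx
}

bn_bwd <- function(dy, bn, cache, G = NULL, key = NULL) {
  d <- dim(dy)
  dym <- matrix(dy, prod(d[1:3]), d[4])
  xhat <- cache$xhat
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  n <- nrow(dym)
  dxhat <- sweep(dym, 2, bn$gamma, `*`)
  dx <- sweep(
    dxhat - matrix(colMeans(dxhat), n, d[4], byrow = TRUE) -
      xhat * matrix(colMeans(dxhat * xhat), n, d[4], byrow = TRUE),
    2, inv_sd, `*`)
  dim(dx) <- d
  if (!is.null(G)) {
    G[[paste0(key, ".gamma")]] <- dgamma
    G[[paste0(key, ".beta")]] <- dbeta
    G[[paste0(key, ".stats")]] <- list(mu = cache$mu, v = cache$v)
  }
  dx
}

add_center <- function(acc, dcrop) {
  da <- dim(acc); dc <- dim(dcrop)
  mh <- (da[2] - dc[2]) %/% 2L
  mw <- (da[3] - dc[3]) %/% 2L
  acc[, mh + seq_len(dc[2]), mw + seq_len(dc[3]), ] <-
    acc[, mh + seq_len(dc[2]), mw + seq_len(dc[3]), , drop = FALSE] + dcrop
  acc
}

avgpool_bwd <- function(dy, prepool_dim) {
  dx <- array(0, prepool_dim)
  od <- dim(dy)
  r <- seq_len(od[2]); c <- seq_len(od[3])
  q <- dy / 4
  dx[, 2L * r - 1L, 2L * c - 1L, ] <- q
  dx[, 2L * r, 2L * c - 1L, ] <- q
  dx[, 2L * r - 1L, 2L * c, ] <- q
  dx[, 2L * r, 2L * c, ] <- q
  dx
}

split_channels <- function(du, widths) {
  d <- dim(du)
  out <- vector("list", length(widths))
  at <- 0L
  for (k in seq_along(widths)) {
    out[[k]] <- du[, , , at + seq_len(widths[k]), drop = FALSE]
    at <- at + widths[k]
  }
  out
}

block_bwd <- function(dout, layers, cache, n3, G, key) {
  feat_dims <- cache$feat_dims
  widths <- vapply(feat_dims, function(d) d[4], numeric(1))
  dfeats <- lapply(feat_dims, function(d) array(0, d))
  # output 1x1
  dabn <- dout * cache$relu_out
  da <- bn_bwd(dabn, layers$bn1_out, cache$bn1c_out, G,
               paste0(key, ".bn1_out"))
  du <- conv_bwd(cache$u_out, layers$conv1_out, da, G,
                 paste0(key, ".conv1_out"))
  pieces <- split_channels(du, widths)
  for (piece in seq_along(dfeats)) {
    dfeats[[piece]] <- add_center(dfeats[[piece]], pieces[[piece]])
  }
  for (j in seq(n3, 1L)) {
    dzr <- dfeats[[j + 1L]]
    dzbn <- dzr * cache[[paste0("relu3_", j)]]
    dz <- bn_bwd(dzbn, layers[[paste0("bn3_", j)]],
                 cache[[paste0("bn3c_", j)]], G, paste0(key, ".bn3_", j))
    dy <- conv_bwd(cache[[paste0("y_", j)]], layers[[paste0("conv3_", j)]],
                   dz, G, paste0(key, ".conv3_", j))
    dabn <- dy * cache[[paste0("relu1_", j)]]
    da <- bn_bwd(dabn, layers[[paste0("bn1_", j)]],
                 cache[[paste0("bn1c_", j)]], G, paste0(key, ".bn1_", j))
    du <- conv_bwd(cache[[paste0("u_", j)]], layers[[paste0("conv1_", j)]],
                   da, G, paste0(key, ".conv1_", j))
    pieces <- split_channels(du, widths[seq_len(j)])
    for (piece in seq_len(j)) {
      dfeats[[piece]] <- add_center(dfeats[[piece]], pieces[[piece]])
    }
  }
  dfeats[[1L]]
}

# loss + gradient of one minibatch; supervision at the center output position
network_grad <- function(net, x, y_onehot, l2 = 1e-4) {
  cfg <- net$config
  fw <- network_logits(net, x, training = TRUE)
  logits <- fw$logits
  caches <- fw$caches
  od <- dim(logits)
  rc <- (od[2] + 1L) %/% 2L; cc <- (od[3] + 1L) %/% 2L
  lc <- logits[, rc, cc, , drop = FALSE]
  dim(lc) <- c(od[1], od[4])
  lc <- lc - apply(lc, 1, max)
  p <- exp(lc) / rowSums(exp(lc))
  n <- od[1]
  loss <- -mean(log(pmax(rowSums(p * y_onehot), 1e-12)))
  acc <- mean(max.col(p) == max.col(y_onehot))
  G <- new.env(parent = emptyenv())
  dlogits <- array(0, od)
  dlogits[, rc, cc, ] <- (p - y_onehot) / n
  dh <- conv_bwd(caches$final_in, net$final_conv, dlogits, G, "final_conv")
  for (b in seq(length(net$blocks), 1L)) {
    if (b < length(net$blocks)) {
      dh <- avgpool_bwd(dh, caches[[paste0("trans_prepool_dim_", b)]])
      dabn <- dh * caches[[paste0("trans_relu_", b)]]
      da <- bn_bwd(dabn, net$trans[[b]]$bn, caches[[paste0("trans_bnc_", b)]],
                   G, paste0("trans.", b, ".bn"))
      dh <- conv_bwd(caches[[paste0("trans_in_", b)]], net$trans[[b]]$conv,
                     da, G, paste0("trans.", b, ".conv"))
    }
    dh <- block_bwd(dh, net$blocks[[b]], caches[[paste0("block_cache_", b)]],
                    cfg$convs_3x3_per_block, G, paste0("blocks.", b))
  }
  # L2 penalty on convolution weights: loss += l2 * sum(W^2)
  grads <- as.list(G)
  for (k in names(grads)) {
    if (endsWith(k, ".W")) {
      W <- param_get(net, k)
      grads[[k]] <- grads[[k]] + 2 * l2 * W
      loss <- loss + l2 * sum(W^2)
    }
  }
  list(loss = loss, acc = acc, grads = grads)
}

# ---- parameter addressing ---------------------------------------------------

param_path <- function(key) strsplit(key, ".", fixed = TRUE)[[1]]

param_get <- function(net, key) {
  p <- param_path(key)
  node <- net
  for (s in p) {
    node <- if (grepl("^[0-9]+$", s)) node[[as.integer(s)]] else node[[s]]
  }
  node
}

param_set <- function(net, key, value) {
  p <- param_path(key)
  expr <- "net"
  for (s in p) {
    expr <- if (grepl("^[0-9]+$", s)) {
      sprintf("%s[[%s]]", expr, s)
    } else {
      sprintf("%s[[\"%s\"]]", expr, s)
    }
  }
  eval(parse(text = paste0(expr, " <- value")))
  net
}

#' Apply one Adam update
#'
#' @param net A `dense_network`.
#' @param grads Flat named gradient list from the internal backprop.
#' @param state Adam state environment (created on first call).
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer (framework
#'   defaults).
#' @return The updated network.
#' @keywords internal
adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- (state$t %||% 0L) + 1L
  t <- state$t
  for (k in names(grads)) {
    if (endsWith(k, ".stats")) {
      # batch-norm running statistics (momentum 0.9)
      base <- sub("\\.stats$", "", k)
      bn_mu <- param_get(net, paste0(base, ".running_mean"))
      bn_v <- param_get(net, paste0(base, ".running_var"))
      net <- param_set(net, paste0(base, ".running_mean"),
                       0.9 * bn_mu + 0.1 * grads[[k]]$mu)
      net <- param_set(net, paste0(base, ".running_var"),
                       0.9 * bn_v + 0.1 * grads[[k]]$v)
      next
    }
    g <- grads[[k]]
    m <- state[[paste0(k, ".m")]] %||% (g * 0)
    v <- state[[paste0(k, ".v")]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[paste0(k, ".m")]] <- m
    state[[paste0(k, ".v")]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    net <- param_set(net, k, param_get(net, k) - lr * mhat / (sqrt(vhat) + eps))
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Learning-rate schedule and early stopping as a pure function
#'
#' Given a validation-accuracy sequence, replays the training schedule:
#' "improvement" means strictly exceeding the best value so far; after
#' `lr_patience` consecutive epochs without improvement the learning rate is
#' divided by `drop_factor` (and the patience counter restarts); after
#' `early_stop_patience` epochs without improvement training stops; training
#' never exceeds `max_epochs`.
#'
#' @param val_acc Numeric vector of per-epoch validation accuracies.
#' @param lr_init Initial learning rate.
#' @param drop_factor Factor the learning rate is divided by.
#' @param lr_patience Epochs without improvement before a drop.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param max_epochs Hard epoch cap.
#' @return Tibble with `epoch`, `val_acc`, `lr` (rate used during that
#'   epoch), `best_so_far`, `stopped` (TRUE on the epoch training halts).
#' @export
lr_schedule <- function(val_acc, lr_init = 1e-4, drop_factor = 10,
                        lr_patience = 4, early_stop_patience = 20,
                        max_epochs = 200) {
  n <- min(length(val_acc), max_epochs)
  lr <- lr_init
  best <- -Inf
  since_best <- 0L
  since_drop <- 0L
  out <- vector("list", n)
  for (e in seq_len(n)) {
    lr_used <- lr
    if (val_acc[e] > best) {
      best <- val_acc[e]
      since_best <- 0L
      since_drop <- 0L
    } else {
      since_best <- since_best + 1L
      since_drop <- since_drop + 1L
    }
    stopped <- since_best >= early_stop_patience || e == n
    if (since_drop >= lr_patience) {
      lr <- lr / drop_factor
      since_drop <- 0L
    }
    out[[e]] <- tibble::tibble(epoch = e, val_acc = val_acc[e], lr = lr_used,
                               best_so_far = best, stopped = stopped)
    if (since_best >= early_stop_patience) break
  }
  dplyr::bind_rows(out)
}

#' Train the network on patch streams
#'
#' Minimizes categorical cross-entropy with L2 weight decay using Adam,
#' following the study schedule: drop the learning rate by `lr_drop_factor`
#' after `lr_patience_epochs` epochs without validation-accuracy
#' improvement, stop early after `early_stop_patience` epochs without
#' improvement, and return the best-validation checkpoint.
#'
#' @param net A `dense_network`.
#' @param train_stream,val_stream Functions of an epoch index returning
#'   `list(x = (N, H, W, C) array, y = labels in 1..n_classes)`.
#' @param config A [train_config()].
#' @return List with `net` (best checkpoint) and `history` tibble
#'   (`epoch`, `lr`, `train_acc`, `val_acc`, `train_loss`).
#' @export
train_network <- function(net, train_stream, val_stream, config) {
  state <- new.env(parent = emptyenv())
  lr <- config$lr_init
  best <- -Inf; best_net <- net
  since_best <- 0L; since_drop <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    tr <- train_stream(epoch)
    if (is.null(tr) || length(tr$y) == 0L) stop("empty training stream")
    ord <- with_seed(derive_seed(config$seed, 31L, epoch),
                     sample.int(length(tr$y)))
    losses <- accs <- c()
    for (i0 in seq(1L, length(ord), by = config$batch_size)) {
      take <- ord[i0:min(i0 + config$batch_size - 1L, length(ord))]
      xb <- tr$x[take, , , , drop = FALSE]
      yb <- diag(net$config$n_classes)[tr$y[take], , drop = FALSE]
      g <- network_grad(net, xb, yb, l2 = config$l2_weight)
      net <- adam_step(net, g$grads, state, lr)
      losses <- c(losses, g$loss); accs <- c(accs, g$acc)
    }
    va <- val_stream(epoch)
    vp <- network_forward(net, va$x)
    ctr_r <- (dim(vp)[2] + 1L) %/% 2L; ctr_c <- (dim(vp)[3] + 1L) %/% 2L
    vpred <- max.col(matrix(vp[, ctr_r, ctr_c, ], dim(vp)[1], dim(vp)[4]))
    val_acc <- mean(vpred == va$y)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      train_acc = mean(accs), val_acc = val_acc)
    if (val_acc > best) {
      best <- val_acc; best_net <- net
      since_best <- 0L; since_drop <- 0L
    } else {
      since_best <- since_best + 1L
      since_drop <- since_drop + 1L
    }
    if (since_best >= config$early_stop_patience) break
    if (since_drop >= config$lr_patience_epochs) {
      lr <- lr / config$lr_drop_factor
      since_drop <- 0L
    }
  }
  list(net = best_net, history = dplyr::bind_rows(history))
}
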