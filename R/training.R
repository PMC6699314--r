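#' Training configuration
#'
#' The published schedule: ADAM with initial learning rate `1e-3` decayed
#' by 0.98 per epoch and restored to the initial value every 100 epochs,
#' L2 weight decay `1e-4` added to the loss, minibatch of 16 images with
#' drop-last batching, per-epoch shuffling, He-initialized weights, and
#' best-model selection on validation mean Dice.
#'
#' @param lr_init initial learning rate.
#' @param lr_decay per-epoch decay factor.
#' @param restart_period epochs between learning-rate restarts.
#' @param l2 L2 weight-decay coefficient (applied to convolution kernels).
#' @param minibatch minibatch size.
#' @param epochs maximum number of epochs (at least 1 is always run).
#' @param loss loss variant: `"igd"`, `"gdl"` or `"ce"`.
#' @param augment apply on-the-fly augmentation to training minibatches.
#' @param augment_cfg an [augment_config()].
#' @param patience early-stop patience on validation mean Dice (epochs).
#' @param seed seed controlling initialization, shuffling, augmentation
#'   and dropout.
#' @param adam_beta1,adam_beta2,adam_eps ADAM moment parameters (published
#'   defaults).
#' @param bn_finalize recompute batch-norm population statistics over the
#'   training set after training (one extra forward pass), as the reference
#'   training procedure does; the per-epoch history still uses the cheap
#'   moving statistics.
#' @return a `train_config`.
#' @export
train_config <- function(lr_init = 1e-3, lr_decay = 0.98,
                         restart_period = 100L, l2 = 1e-4,
                         minibatch = 16L, epochs = 200L,
                         loss = c("igd", "ce", "gdl"), augment = TRUE,
                         augment_cfg = augment_config(), patience = 50L,
                         seed = 1L, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, bn_finalize = TRUE) {
  loss <- match.arg(loss)
  stopifnot(lr_init > 0, lr_decay > 0, restart_period >= 1, minibatch >= 1,
            epochs >= 0, l2 >= 0, patience >= 1)
  structure(list(lr_init = lr_init, lr_decay = lr_decay,
                 restart_period = as.integer(restart_period), l2 = l2,
                 minibatch = as.integer(minibatch),
                 epochs = max(1L, as.integer(epochs)), loss = loss,
                 augment = isTRUE(augment), augment_cfg = augment_cfg,
                 patience = as.integer(patience), seed = as.integer(seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, bn_finalize = isTRUE(bn_finalize)),
            class = "train_config")
}

#' Learning-rate schedule with warm restarts
#'
#' `lr(epoch) = lr_init * lr_decay^((epoch - 1) mod restart_period)`:
#' exponential decay restored to the initial rate every `restart_period`
#' epochs.
#'
#' @param epoch 1-based epoch index.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 1))
  config$lr_init * config$lr_decay^((epoch - 1) %% config$restart_period)
}

#' Number of (augmented) images presented to the network
#'
#' With drop-last batching every epoch presents
#' `floor(n_train / minibatch) * minibatch` images, each a fresh random
#' augmentation, so over training the network effectively sees
#' `floor(n_train / minibatch) * minibatch * epochs` distinct images.
#'
#' @param n_train training-set size.
#' @param minibatch minibatch size.
#' @param epochs number of epochs.
#' @return integer count.
#' @export
images_seen <- function(n_train, minibatch, epochs) {
  stopifnot(n_train >= 1, minibatch >= 1, epochs >= 1)
  (n_train %/% minibatch) * minibatch * epochs
}

#' Load a manifest into memory as preprocessed tensors
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param pre_cfg a [preprocess_config()].
#' @param split optional split tag filter.
#' @return `list(images, labels)`: unit-float matrices and label maps at
#'   the network input size.
#' @export
load_dataset <- function(manifest, pre_cfg = preprocess_config(),
                         split = NULL) {
  m <- manifest
  if (!is.null(split)) m <- m[m$split == split, , drop = FALSE]
  if (nrow(m) == 0) stop("no records to load")
  images <- vector("list", nrow(m))
  labels <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    img <- read_image(m$image[i])
    images[[i]] <- unclass(preprocess_pipeline(img, pre_cfg))
    attributes(images[[i]]) <- attributes(images[[i]])["dim"]
    lab <- read_label(m$label[i])
    labels[[i]] <- resize_label(lab, pre_cfg$rows, pre_cfg$cols)
  }
  list(images = images, labels = labels)
}

# Stack a list of H x W matrices into the (H*W*N) x 1 network input.
stack_batch <- function(images) {
  matrix(unlist(images, use.names = FALSE), ncol = 1L)
}

# Mean foreground Dice of a probability map batch against labels.
batch_mean_dice <- function(probs, labels, H, W) {
  n <- length(labels)
  pred <- max.col(probs, ties.method = "first")
  preds <- lapply(seq_len(n), function(i) {
    label_map(matrix(as.integer(pred[(i - 1) * H * W + seq_len(H * W)]), H, W))
  })
  evaluate(preds, labels)$mean_dice
}

adam_step <- function(params, grads, mstate, vstate, lr, t, cfg) {
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
    vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (mstate[[nm]] / corr1) / (sqrt(vstate[[nm]] / corr2) + cfg$adam_eps)
  }
  list(params = params, m = mstate, v = vstate)
}

#' Train a segmentation network
#'
#' Per epoch: shuffle the training set (seeded), iterate drop-last
#' minibatches, apply on-the-fly augmentation (never persisted; the only
#' extra storage is the current minibatch), forward, compute the
#' configured loss per item plus the L2 penalty, back-propagate and take
#' an ADAM step at [lr_schedule()]'s rate; then evaluate mean Dice on the
#' validation set. The returned network carries the weights of the epoch
#' with the highest validation mean Dice. Fully reproducible for fixed
#' `(seed, config, data)` on one device.
#'
#' @param net a `heartseg_net` from [build_network()].
#' @param train_data,valid_data datasets from [load_dataset()] (or a
#'   manifest data.frame, loaded with `pre_cfg`).
#' @param config a [train_config()].
#' @param pre_cfg preprocessing configuration used when manifests are
#'   given.
#' @param verbose print one line per epoch.
#' @return `list(net, history)`: the best network and a data.frame with
#'   per-epoch `epoch`, `lr`, `train_loss`, `train_dice`, `valid_loss`,
#'   `valid_dice`.
#' @export
train <- function(net, train_data, valid_data, config = train_config(),
                  pre_cfg = preprocess_config(), verbose = FALSE) {
  if (is.data.frame(train_data)) train_data <- load_dataset(train_data, pre_cfg)
  if (is.data.frame(valid_data)) valid_data <- load_dataset(valid_data, pre_cfg)
  n_train <- length(train_data$images)
  if (length(valid_data$images) == 0) stop("empty validation set")
  spec <- net$spec
  H <- spec$rows; W <- spec$cols; K <- spec$classes
  bs <- min(config$minibatch, n_train)
  n_batches <- n_train %/% bs
  if (n_batches == 0) stop("training set smaller than one minibatch")
  rng <- rng_new(config$seed)
  params <- net$params
  state <- net$state
  mstate <- lapply(params, function(a) a * 0)
  vstate <- lapply(params, function(a) a * 0)
  is_kernel <- grepl("\\.W[ab12s]?$", names(params))
  history <- data.frame()
  best <- list(dice = -Inf, params = params, state = state)
  t_step <- 0L
  no_improve <- 0L

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    order <- rng_sample(rng, seq_len(n_train))
    ep_loss <- 0; ep_dice <- 0
    for (b in seq_len(n_batches)) {
      idx <- order[(b - 1) * bs + seq_len(bs)]
      imgs <- train_data$images[idx]
      labs <- train_data$labels[idx]
      if (config$augment) {
        aug <- augment_minibatch(imgs, labs, config$augment_cfg, rng)
        imgs <- aug$images
        labs <- aug$labels
      }
      x <- stack_batch(imgs)
      work_net <- structure(list(spec = spec, params = params, state = state),
                            class = "heartseg_net")
      fw <- net_forward(work_net, x, n = bs, training = TRUE, rng = rng)
      state <- fw$state
      probs <- fw$probs
      M <- H * W
      dprobs <- matrix(0, nrow(probs), K)
      loss_sum <- 0
      for (i in seq_len(bs)) {
        rows_i <- (i - 1) * M + seq_len(M)
        Yi <- t(probs[rows_i, , drop = FALSE]) # K x M
        Ti <- one_hot_encode(labs[[i]], K)
        sl <- segmentation_loss(Yi, Ti, config$loss)
        loss_sum <- loss_sum + sl$loss
        dprobs[rows_i, ] <- t(sl$grad) / bs
      }
      loss <- loss_sum / bs
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      if (config$l2 > 0)
        loss <- loss + config$l2 *
          sum(vapply(params[is_kernel], function(a) sum(a * a), numeric(1)))
      # softmax backward: dlogits = P * (g - rowSums(g * P))
      inner <- rowSums(dprobs * probs)
      dlogits <- probs * (dprobs - inner)
      grads <- net_backward(work_net, fw$cache, dlogits)
      if (config$l2 > 0) {
        for (nm in names(params)[is_kernel])
          grads[[nm]] <- grads[[nm]] + 2 * config$l2 * params[[nm]]
      }
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, mstate, vstate, lr, t_step, config)
      params <- upd$params; mstate <- upd$m; vstate <- upd$v
      ep_loss <- ep_loss + loss
      ep_dice <- ep_dice + batch_mean_dice(probs, labs, H, W)
    }
    eval_net <- structure(list(spec = spec, params = params, state = state),
                          class = "heartseg_net")
    vl <- validate_epoch(eval_net, valid_data, config$loss)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / n_batches,
      train_dice = ep_dice / n_batches, valid_loss = vl$loss,
      valid_dice = vl$dice))
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.2e  train loss %.4f dice %.3f  valid loss %.4f dice %.3f",
        epoch, lr, ep_loss / n_batches, ep_dice / n_batches, vl$loss, vl$dice))
    if (is.finite(vl$dice) && vl$dice > best$dice) {
      best <- list(dice = vl$dice, params = params, state = state)
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (no_improve >= config$patience) break
    }
  }
  out_net <- structure(list(spec = spec, params = best$params,
                            state = best$state),
                       class = "heartseg_net")
  if (isTRUE(config$bn_finalize) && spec$batch_norm)
    out_net <- finalize_bn_stats(out_net, train_data, bs)
  list(net = out_net, history = history)
}

#' Finalize batch-norm statistics over a dataset
#'
#' Replaces the exponentially-weighted running statistics accumulated
#' during training with exact population moments estimated in one pass
#' over the (unaugmented) training images, the way the reference training
#' procedure finalizes batch normalization after the last iteration.
#' Dropout is disabled during the pass; weights are untouched.
#'
#' @param net a `heartseg_net` with batch normalization.
#' @param data dataset from [load_dataset()].
#' @param minibatch batch size for the collection pass.
#' @return the network with finalized running statistics.
#' @export
finalize_bn_stats <- function(net, data, minibatch = 16L) {
  spec <- net$spec
  if (!spec$batch_norm) return(net)
  spec0 <- spec
  spec0$dropout <- 0
  probe <- structure(list(spec = spec0, params = net$params,
                          state = net$state),
                     class = "heartseg_net")
  n <- length(data$images)
  bs <- min(minibatch, n)
  n_batches <- max(1L, n %/% bs)
  bn_names <- grep("\\.(m|v)$", names(net$state), value = TRUE)
  m_names <- grep("\\.m$", bn_names, value = TRUE)
  acc_mu <- acc_mu2 <- acc_v <- NULL
  for (b in seq_len(n_batches)) {
    idx <- (b - 1) * bs + seq_len(bs)
    x <- stack_batch(data$images[idx])
    st0 <- probe$state
    fw <- net_forward(probe, x, n = bs, training = TRUE)
    st1 <- fw$state
    # recover this batch's moments from the momentum-0.9 state update
    mu <- lapply(m_names, function(nm) 10 * st1[[nm]] - 9 * st0[[nm]])
    v <- lapply(m_names, function(nm) {
      vn <- sub("\\.m$", ".v", nm)
      10 * st1[[vn]] - 9 * st0[[vn]]
    })
    if (is.null(acc_mu)) {
      acc_mu <- mu
      acc_mu2 <- lapply(mu, function(m) m * m)
      acc_v <- v
    } else {
      acc_mu <- Map(`+`, acc_mu, mu)
      acc_mu2 <- Map(`+`, acc_mu2, lapply(mu, function(m) m * m))
      acc_v <- Map(`+`, acc_v, v)
    }
  }
  state <- net$state
  for (j in seq_along(m_names)) {
    pm <- acc_mu[[j]] / n_batches
    pv <- acc_v[[j]] / n_batches + acc_mu2[[j]] / n_batches - pm * pm
    state[[m_names[j]]] <- pm
    state[[sub("\\.m$", ".v", m_names[j])]] <- pmax(pv, 0)
  }
  structure(list(spec = spec, params = net$params, state = state),
            class = "heartseg_net")
}

validate_epoch <- function(net, valid_data, loss_variant) {
  spec <- net$spec
  H <- spec$rows; W <- spec$cols; K <- spec$classes
  n <- length(valid_data$images)
  M <- H * W
  loss_sum <- 0
  preds <- vector("list", n)
  # forward in chunks to bound memory
  chunk <- 16L
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    x <- stack_batch(valid_data$images[idx])
    fw <- net_forward(net, x, n = length(idx), training = FALSE)
    for (j in seq_along(idx)) {
      rows_j <- (j - 1) * M + seq_len(M)
      Yj <- t(fw$probs[rows_j, , drop = FALSE])
      Tj <- one_hot_encode(valid_data$labels[[idx[j]]], K)
      loss_sum <- loss_sum +
        segmentation_loss(Yj, Tj, loss_variant)$loss
      pj <- max.col(fw$probs[rows_j, , drop = FALSE], ties.method = "first")
      preds[[idx[j]]] <- label_map(matrix(as.integer(pj), H, W))
    }
  }
  rep <- evaluate(preds, valid_data$labels)
  list(loss = loss_sum / n, dice = rep$mean_dice)
}

#' Smooth a training history by moving average
#'
#' Centered moving average with edge truncation applied to the loss and
#' Dice columns; `window = 1` is the identity.
#'
#' @param history history data.frame from [train()].
#' @param window odd window length in epochs.
#' @return smoothed history.
#' @export
smooth_history <- function(history, window = 1L) {
  stopifnot(window >= 1)
  sm <- function(v) {
    r <- (window - 1) %/% 2
    vapply(seq_along(v), function(i) {
      mean(v[max(1, i - r):min(length(v), i + r)])
    }, numeric(1))
  }
  out <- history
  for (col in intersect(c("train_loss", "train_dice", "valid_loss",
                          "valid_dice"), names(history)))
    out[[col]] <- sm(history[[col]])
  out
}

#' Plot training curves
#'
#' @param history history data.frame from [train()].
#' @param window moving-average window for display.
#' @export
plot_history <- function(history, window = 1L) {
  h <- smooth_history(history, window)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_dice, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "mean Dice", ylim = c(0, 1))
  graphics::lines(h$epoch, h$valid_dice, col = "firebrick")
  graphics::legend("bottomright", c("train", "valid"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss")
  graphics::lines(h$epoch, h$valid_loss, col = "firebrick")
  invisible(h)
}

#' Train and evaluate a grid of ablation arms
#'
#' Each arm trains the chosen architecture with a loss variant and
#' augmentation flag under identical seeds and data, then evaluates
#' per-class Dice/IoU on the validation and (optionally) test sets,
#' producing one row per arm in the layout of the usual
#' model x loss x augmentation comparison tables.
#'
#' @param arms data.frame with columns `model` ("residual" or "unet"),
#'   `loss` ("igd", "gdl", "ce") and `augment` (logical).
#' @param spec base [net_spec()] (its `arch` is overridden per arm).
#' @param train_data,valid_data,test_data datasets from [load_dataset()].
#' @param config base [train_config()] (loss/augment overridden per arm).
#' @return data.frame with one row per arm: mean and per-class Dice/IoU on
#'   each evaluated split.
#' @export
run_ablation <- function(arms, spec, train_data, valid_data,
                         test_data = NULL, config = train_config()) {
  stopifnot(nrow(arms) >= 1)
  rows <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    s <- spec
    s$arch <- if (arms$model[a] == "unet") "unet" else "residual"
    cfg <- config
    cfg$loss <- arms$loss[a]
    cfg$augment <- isTRUE(arms$augment[a])
    net <- build_network(s, seed = config$seed)
    fit <- train(net, train_data, valid_data, cfg)
    sets <- list(valid = valid_data)
    if (!is.null(test_data)) sets$test <- test_data
    row <- data.frame(model = arms$model[a], loss = arms$loss[a],
                      augment = cfg$augment)
    for (sn in names(sets)) {
      rep <- evaluate_dataset(fit$net, sets[[sn]])
      row[[paste0(sn, "_mean_dice")]] <- rep$mean_dice
      row[[paste0(sn, "_mean_iou")]] <- rep$mean_iou
      for (i in seq_len(nrow(rep$per_class))) {
        k <- rep$per_class$class[i]
        row[[paste0(sn, "_dice_k", k)]] <- rep$per_class$dice[i]
      }
    }
    rows[[a]] <- row
  }
  do.call(rbind, rows)
}

#' Evaluate a network on a dataset
#'
#' @param net a `heartseg_net`.
#' @param data dataset from [load_dataset()].
#' @return a `metrics_report`.
#' @export
evaluate_dataset <- function(net, data) {
  preds <- lapply(data$images, function(im) predict(net, im))
  evaluate(preds, data$labels)
}
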