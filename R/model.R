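#' Network architecture specification
#'
#' Declarative description of the residual encoder-decoder segmenter: an
#' encoder of `levels` stages (residual block then 2x2 max pooling) with
#' channel widths `base_width * growth^(level-1)`, a bottleneck residual
#' block followed by dropout, a decoder of `levels` stages (2x2 transposed
#' convolution halving the channels, concatenation with the matching
#' encoder feature map, residual block), and a 1x1 convolution head mapping
#' `base_width` channels to `classes` followed by a per-pixel SoftMax.
#' The default (base 24, growth 2, 4 levels) realizes the published
#' architecture with widths 24-48-96-192 and a 384-channel bottleneck.
#'
#' @param rows,cols input grid; must be divisible by `2^levels`.
#' @param in_channels input channels (1 for grayscale).
#' @param classes number of output classes K.
#' @param base_width channels of the first encoder block.
#' @param levels number of pooling levels.
#' @param growth width growth factor per level.
#' @param dropout dropout rate at the bottleneck, in \[0, 1).
#' @param batch_norm use batch normalization inside the blocks.
#' @return a `net_spec`.
#' @export
net_spec <- function(rows = 160L, cols = 128L, in_channels = 1L,
                     classes = 4L, base_width = 24L, levels = 4L,
                     growth = 2L, dropout = 0.5, batch_norm = TRUE) {
  stopifnot(base_width >= 1, classes >= 2, levels >= 1,
            dropout >= 0, dropout < 1)
  if (rows %% 2^levels != 0 || cols %% 2^levels != 0)
    stop(sprintf("input %dx%d not divisible by 2^%d", rows, cols, levels))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 in_channels = as.integer(in_channels),
                 classes = as.integer(classes),
                 base_width = as.integer(base_width),
                 levels = as.integer(levels), growth = as.integer(growth),
                 dropout = dropout, batch_norm = isTRUE(batch_norm),
                 arch = "residual"),
            class = "net_spec")
}

spec_widths <- function(spec) spec$base_width * spec$growth^(0:(spec$levels - 1))

#' Describe a residual block and count its parameters
#'
#' The block is: main path 3x3 conv -> BN -> ReLU -> 3x3 conv -> BN;
#' shortcut 1x1 conv -> BN; output ReLU(main + shortcut); stride 1 with
#' same-padding, so the spatial size is preserved. Convolution parameters
#' total `9*cin*cout + 9*cout^2 + cin*cout`; each BN contributes `2*cout`
#' affine terms (without BN the three convolutions carry biases instead).
#'
#' @param in_channels,out_channels channel counts (>= 1).
#' @param batch_norm include batch normalization.
#' @return list with the layer sequence and the parameter accounting.
#' @export
build_residual_block <- function(in_channels, out_channels,
                                 batch_norm = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1)
  conv <- 9 * in_channels * out_channels + 9 * out_channels^2 +
    in_channels * out_channels
  extra <- if (batch_norm) 6 * out_channels else 3 * out_channels
  list(
    main = c("conv3x3", if (batch_norm) "bn", "relu",
             "conv3x3", if (batch_norm) "bn"),
    shortcut = c("conv1x1", if (batch_norm) "bn"),
    combine = "relu(main + shortcut)",
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    conv_params = conv,
    affine_params = extra,
    total_params = conv + extra)
}

#' Build a trainable network from a specification
#'
#' Weights use He initialization (zero-mean normal with variance
#' `2 / fan_in`); batch-norm scale/offset start at 1/0.
#'
#' @param spec a [net_spec()] (or [unet_spec()]).
#' @param seed seed for the weight initialization stream.
#' @return a `heartseg_net` with elements `spec`, `params` (flat named list
#'   of trainable arrays) and `state` (batch-norm running statistics).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "net_spec"))
  rng <- rng_new(seed)
  w <- spec_widths(spec)
  L <- spec$levels
  bn <- spec$batch_norm
  block_init <- if (spec$arch == "residual") rb_init else dc_init
  block_state <- if (spec$arch == "residual") rb_state_init else dc_state_init
  params <- list(); state <- list()
  cin <- spec$in_channels
  for (l in seq_len(L)) {
    params <- block_init(params, paste0("enc", l), cin, w[l], bn, rng)
    state <- block_state(state, paste0("enc", l), w[l], bn)
    cin <- w[l]
  }
  wb <- spec$base_width * spec$growth^L
  params <- block_init(params, "bottom", cin, wb, bn, rng)
  state <- block_state(state, "bottom", wb, bn)
  cprev <- wb
  for (l in rev(seq_len(L))) {
    params <- upconv_init(params, paste0("dec", l, ".up"), cprev, w[l], rng)
    params <- block_init(params, paste0("dec", l, ".block"), 2 * w[l], w[l],
                         bn, rng)
    state <- block_state(state, paste0("dec", l, ".block"), w[l], bn)
    cprev <- w[l]
  }
  params[["head.W"]] <- matrix(rng_rnorm(rng, w[1] * spec$classes, 0,
                                         sqrt(2 / w[1])), w[1], spec$classes)
  params[["head.b"]] <- rep(0, spec$classes)
  structure(list(spec = spec, params = params, state = state),
            class = "heartseg_net")
}

#' Count trainable parameters
#'
#' Exact count of all trainable scalars: convolution kernels, biases and
#' batch-norm scale/offset pairs (running statistics are not trainable and
#' are not counted).
#'
#' @param net a `heartseg_net`.
#' @return integer count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.heartseg_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<heartseg_net %s: %dx%dx%d -> K=%d, base %d, %d levels, %s params>\n",
    s$arch, s$rows, s$cols, s$in_channels, s$classes, s$base_width,
    s$levels, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass of the network
#'
#' @param net a `heartseg_net`.
#' @param x input feature matrix, `(rows*cols*N) x in_channels`, unit
#'   scale.
#' @param n minibatch size N.
#' @param training training mode: batch statistics for BN, dropout active
#'   (requires `rng`), caches retained for [net_backward()].
#' @param rng stream for dropout masks (training only).
#' @return `list(logits, probs, cache, state)`; `probs` rows sum to 1.
#' @export
net_forward <- function(net, x, n = 1L, training = FALSE, rng = NULL) {
  spec <- net$spec
  p <- net$params
  st <- list2env(net$state, parent = emptyenv())
  L <- spec$levels
  bn <- spec$batch_norm
  fwd <- if (spec$arch == "residual") rb_forward else dc_forward
  stopifnot(nrow(x) == spec$rows * spec$cols * n)
  sp <- c(spec$rows, spec$cols, n)
  cache <- list(sps = list(), enc = list(), pool_idx = list(), skips = list())
  h <- x
  for (l in seq_len(L)) {
    r <- local_block_forward(fwd, p, st, paste0("enc", l), h, sp, training, bn)
    cache$enc[[l]] <- r$cache
    cache$skips[[l]] <- r$out
    cache$sps[[l]] <- sp
    mp <- maxpool2_fwd(r$out, sp[1], sp[2], sp[3])
    cache$pool_idx[[l]] <- mp$idx
    cache$pool_nrow[[l]] <- nrow(r$out)
    h <- mp$out
    sp <- c(sp[1] %/% 2L, sp[2] %/% 2L, n)
  }
  r <- local_block_forward(fwd, p, st, "bottom", h, sp, training, bn)
  cache$bottom <- r$cache
  h <- r$out
  if (training && spec$dropout > 0) {
    if (is.null(rng)) stop("training-mode forward needs an rng for dropout")
    keep <- 1 - spec$dropout
    mask <- (matrix(rng_runif(rng, length(h)), nrow(h), ncol(h)) < keep) / keep
    h <- h * mask
    cache$drop_mask <- mask
  }
  for (l in rev(seq_len(L))) {
    xin <- h
    up <- upconv_forward(p, paste0("dec", l, ".up"), xin, sp)
    cache$dec_up_in[[l]] <- xin
    cache$dec_up_sp[[l]] <- sp
    sp <- c(sp[1] * 2L, sp[2] * 2L, n)
    cat_in <- cbind(up, cache$skips[[l]])
    r <- local_block_forward(fwd, p, st, paste0("dec", l, ".block"), cat_in,
                             sp, training, bn)
    cache$dec[[l]] <- r$cache
    h <- r$out
  }
  cache$head_in <- h
  logits <- h %*% p[["head.W"]] + rep(p[["head.b"]], each = nrow(h))
  list(logits = logits, probs = softmax_rows(logits), cache = cache,
       state = as.list(st))
}

# Blocks take the state as an environment so running statistics update in
# place during training-mode forwards.
local_block_forward <- function(fwd, p, st_env, prefix, x, sp, training, bn) {
  fwd(p, st_env, prefix, x, sp, training, bn)
}

#' Backward pass: gradients of a scalar loss with respect to all parameters
#'
#' @param net a `heartseg_net`.
#' @param cache forward cache from a training-mode [net_forward()].
#' @param dlogits gradient of the loss with respect to the logits,
#'   same shape as the forward `logits`.
#' @return flat named list of gradients matching `net$params`.
#' @export
net_backward <- function(net, cache, dlogits) {
  spec <- net$spec
  p <- net$params
  L <- spec$levels
  bn <- spec$batch_norm
  bwd <- if (spec$arch == "residual") rb_backward else dc_backward
  w <- spec_widths(spec)
  grads <- list()
  grads[["head.W"]] <- crossprod(cache$head_in, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dx <- dlogits %*% t(p[["head.W"]])
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    r <- bwd(p, paste0("dec", l, ".block"), cache$dec[[l]], dx, grads, bn)
    grads <- r$grads
    dcat <- r$dx
    dup <- dcat[, seq_len(w[l]), drop = FALSE]
    dskips[[l]] <- dcat[, w[l] + seq_len(w[l]), drop = FALSE]
    ru <- upconv_backward(p, paste0("dec", l, ".up"), cache$dec_up_in[[l]],
                          cache$dec_up_sp[[l]], dup, grads)
    grads <- ru$grads
    dx <- ru$dx
  }
  if (!is.null(cache$drop_mask)) dx <- dx * cache$drop_mask
  r <- bwd(p, "bottom", cache$bottom, dx, grads, bn)
  grads <- r$grads
  dx <- r$dx
  for (l in rev(seq_len(L))) {
    dpool <- maxpool2_bwd(dx, cache$pool_idx[[l]], cache$pool_nrow[[l]])
    r <- bwd(p, paste0("enc", l), cache$enc[[l]], dpool + dskips[[l]],
             grads, bn)
    grads <- r$grads
    dx <- r$dx
  }
  grads
}

#' Standard U-Net comparison arm
#'
#' A conventional 4-level U-Net with plain double-convolution blocks (no
#' residual shortcut), widths doubling from `initial_filters`, optional
#' batch normalization, the same 2x2 transposed-convolution decoder, skip
#' concatenations and 1x1 SoftMax head as the proposed network.
#'
#' @param initial_filters width of the first block (64 reproduces the
#'   standard configuration of roughly 3e7 parameters).
#' @param classes number of classes.
#' @param batch_norm use batch normalization.
#' @param rows,cols,levels,dropout as in [net_spec()].
#' @return a `net_spec` with `arch = "unet"`.
#' @export
unet_spec <- function(initial_filters = 64L, classes = 4L, batch_norm = TRUE,
                      rows = 160L, cols = 128L, levels = 4L, dropout = 0.5) {
  s <- net_spec(rows = rows, cols = cols, classes = classes,
                base_width = initial_filters, levels = levels,
                dropout = dropout, batch_norm = batch_norm)
  s$arch <- "unet"
  s
}

#' @rdname unet_spec
#' @param seed weight-initialization seed.
#' @export
build_unet_baseline <- function(initial_filters = 64L, classes = 4L,
                                batch_norm = TRUE, seed = 1L, ...) {
  build_network(unet_spec(initial_filters, classes, batch_norm, ...),
                seed = seed)
}

#' Segment one preprocessed image
#'
#' Runs an evaluation-mode forward pass (dropout off, batch norm using its
#' running statistics) and takes the per-pixel argmax over class
#' probabilities; ties break toward the lower label value.
#'
#' @param object a `heartseg_net`.
#' @param image unit-float image matrix of the spec's input size.
#' @param ... unused.
#' @return a [label_map()].
#' @export
predict.heartseg_net <- function(object, image, ...) {
  spec <- object$spec
  if (nrow(image) != spec$rows || ncol(image) != spec$cols)
    stop(sprintf("expected a %dx%d input, got %dx%d", spec$rows, spec$cols,
                 nrow(image), ncol(image)))
  x <- matrix(as.numeric(image), ncol = 1L)
  fw <- net_forward(object, x, n = 1L, training = FALSE)
  lab <- max.col(fw$probs, ties.method = "first")
  label_map(matrix(as.integer(lab), spec$rows, spec$cols),
            n_classes = spec$classes)
}

#' Save / load a trained network
#'
#' Weights, running statistics and the spec are stored together with a
#' format version tag.
#'
#' @param net a `heartseg_net`.
#' @param path file path (`.rds`).
#' @export
save_network <- function(net, path) {
  saveRDS(list(format = "heartseg-net-v1", spec = net$spec,
               params = net$params, state = net$state), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "heartseg-net-v1"))
    stop("not a heartseg network checkpoint: ", path)
  structure(list(spec = obj$spec, params = obj$params, state = obj$state),
            class = "heartseg_net")
}

#' Per-layer summary of a network
#'
#' @param object a `heartseg_net`.
#' @param ... unused.
#' @return data.frame of parameter array names, shapes and sizes.
#' @export
summary.heartseg_net <- function(object, ...) {
  d <- data.frame(
    layer = names(object$params),
    shape = vapply(object$params, function(a) {
      if (is.matrix(a)) paste(dim(a), collapse = "x") else as.character(length(a))
    }, character(1)),
    n = vapply(object$params, length, integer(1)))
  rownames(d) <- NULL
  attr(d, "total") <- sum(d$n)
  d
}
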