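# Layer primitives for the encoder-decoder networks.
#
# Feature maps are matrices of size (H*W*N) x C: the spatial grid of each
# minibatch item unrolled column-major, items stacked along rows. `sp` is
# the spatial descriptor c(H, W, N). Convolutions run as per-item im2col
# tiles multiplied by the weight matrix with BLAS, fused in compiled code
# (conv3_fwd_cpp / conv3_bwd_cpp) so no batch-sized column matrix is ever
# materialized.

conv3_forward <- function(x, W, sp) {
  conv3_fwd_cpp(x, W, sp[1], sp[2], sp[3])
}

conv3_backward <- function(x, W, sp, dout) {
  conv3_bwd_cpp(x, W, dout, sp[1], sp[2], sp[3])
}

bn_forward <- function(x, g, b, rm, rv, training, eps = 1e-5) {
  if (training) {
    mom <- col_moments_cpp(x)
    mu <- as.numeric(mom$mu)
    v <- as.numeric(mom$v)
    inv <- 1 / sqrt(v + eps)
    new_rm <- 0.9 * rm + 0.1 * mu
    new_rv <- 0.9 * rv + 0.1 * v
  } else {
    mu <- rm; inv <- 1 / sqrt(rv + eps)
    new_rm <- rm; new_rv <- rv
  }
  f <- bn_fwd_cpp(x, g, b, mu, inv)
  list(out = f$out, xhat = f$xhat, inv = inv, rm = new_rm, rv = new_rv)
}

bn_backward <- function(cache, g, dout) {
  bn_bwd_cpp(cache$xhat, cache$inv, g, dout)
}

relu <- function(x) relu_cpp(x)

# Residual block: main path conv3x3 -> BN -> ReLU -> conv3x3 -> BN;
# shortcut conv1x1 -> BN; output ReLU(main + shortcut). When `bn` is off
# the convolutions carry biases instead.
rb_init <- function(params, prefix, cin, cout, bn, rng) {
  he <- function(nr, nc, fan) matrix(rng_rnorm(rng, nr * nc, 0,
                                               sqrt(2 / fan)), nr, nc)
  params[[paste0(prefix, ".Wa")]] <- he(9 * cin, cout, 9 * cin)
  params[[paste0(prefix, ".Wb")]] <- he(9 * cout, cout, 9 * cout)
  params[[paste0(prefix, ".Ws")]] <- he(cin, cout, cin)
  if (bn) {
    for (nm in c("bnA", "bnB", "bnS")) {
      params[[paste0(prefix, ".", nm, ".g")]] <- rep(1, cout)
      params[[paste0(prefix, ".", nm, ".b")]] <- rep(0, cout)
    }
  } else {
    for (nm in c("ba", "bb", "bs"))
      params[[paste0(prefix, ".", nm)]] <- rep(0, cout)
  }
  params
}

rb_state_init <- function(state, prefix, cout, bn) {
  if (bn) {
    for (nm in c("bnA", "bnB", "bnS")) {
      state[[paste0(prefix, ".", nm, ".m")]] <- rep(0, cout)
      state[[paste0(prefix, ".", nm, ".v")]] <- rep(1, cout)
    }
  }
  state
}

rb_forward <- function(p, st, prefix, x, sp, training, bn) {
  nm <- function(s) paste0(prefix, ".", s)
  n <- nrow(x)
  za <- conv3_forward(x, p[[nm("Wa")]], sp)
  if (bn) {
    bA <- bn_forward(za, p[[nm("bnA.g")]], p[[nm("bnA.b")]],
                     st[[nm("bnA.m")]], st[[nm("bnA.v")]], training)
    if (training) { st[[nm("bnA.m")]] <- bA$rm; st[[nm("bnA.v")]] <- bA$rv }
    aa <- bA$out
  } else aa <- za + rep(p[[nm("ba")]], each = n)
  ha <- relu(aa)
  zb <- conv3_forward(ha, p[[nm("Wb")]], sp)
  if (bn) {
    bB <- bn_forward(zb, p[[nm("bnB.g")]], p[[nm("bnB.b")]],
                     st[[nm("bnB.m")]], st[[nm("bnB.v")]], training)
    if (training) { st[[nm("bnB.m")]] <- bB$rm; st[[nm("bnB.v")]] <- bB$rv }
    bb <- bB$out
  } else bb <- zb + rep(p[[nm("bb")]], each = n)
  zs <- x %*% p[[nm("Ws")]]
  if (bn) {
    bS <- bn_forward(zs, p[[nm("bnS.g")]], p[[nm("bnS.b")]],
                     st[[nm("bnS.m")]], st[[nm("bnS.v")]], training)
    if (training) { st[[nm("bnS.m")]] <- bS$rm; st[[nm("bnS.v")]] <- bS$rv }
    bs <- bS$out
  } else bs <- zs + rep(p[[nm("bs")]], each = n)
  pre <- bb + bs
  out <- relu(pre)
  cache <- list(x = x, aa = aa, ha = ha, pre = pre, sp = sp,
                bnA = if (bn) bA[c("xhat", "inv")],
                bnB = if (bn) bB[c("xhat", "inv")],
                bnS = if (bn) bS[c("xhat", "inv")])
  list(out = out, cache = cache)
}

rb_backward <- function(p, prefix, cache, dout, grads, bn) {
  nm <- function(s) paste0(prefix, ".", s)
  sp <- cache$sp
  dpre <- relu_grad_cpp(cache$pre, dout)
  if (bn) {
    gB <- bn_backward(cache$bnB, p[[nm("bnB.g")]], dpre)
    grads[[nm("bnB.g")]] <- gB$dg; grads[[nm("bnB.b")]] <- gB$db
    dzb <- gB$dx
  } else {
    grads[[nm("bb")]] <- colSums(dpre)
    dzb <- dpre
  }
  cb <- conv3_backward(cache$ha, p[[nm("Wb")]], sp, dzb)
  grads[[nm("Wb")]] <- cb$dW
  daa <- relu_grad_cpp(cache$aa, cb$dx)
  if (bn) {
    gA <- bn_backward(cache$bnA, p[[nm("bnA.g")]], daa)
    grads[[nm("bnA.g")]] <- gA$dg; grads[[nm("bnA.b")]] <- gA$db
    dza <- gA$dx
  } else {
    grads[[nm("ba")]] <- colSums(daa)
    dza <- daa
  }
  ca <- conv3_backward(cache$x, p[[nm("Wa")]], sp, dza)
  grads[[nm("Wa")]] <- ca$dW
  if (bn) {
    gS <- bn_backward(cache$bnS, p[[nm("bnS.g")]], dpre)
    grads[[nm("bnS.g")]] <- gS$dg; grads[[nm("bnS.b")]] <- gS$db
    dzs <- gS$dx
  } else {
    grads[[nm("bs")]] <- colSums(dpre)
    dzs <- dpre
  }
  grads[[nm("Ws")]] <- crossprod(cache$x, dzs)
  list(dx = ca$dx + dzs %*% t(p[[nm("Ws")]]), grads = grads)
}

# Plain double-convolution block (conv3x3 -> [BN] -> ReLU, twice): the
# building block of the standard U-Net comparison arm.
dc_init <- function(params, prefix, cin, cout, bn, rng) {
  he <- function(nr, nc, fan) matrix(rng_rnorm(rng, nr * nc, 0,
                                               sqrt(2 / fan)), nr, nc)
  params[[paste0(prefix, ".W1")]] <- he(9 * cin, cout, 9 * cin)
  params[[paste0(prefix, ".W2")]] <- he(9 * cout, cout, 9 * cout)
  if (bn) {
    for (nm in c("bn1", "bn2")) {
      params[[paste0(prefix, ".", nm, ".g")]] <- rep(1, cout)
      params[[paste0(prefix, ".", nm, ".b")]] <- rep(0, cout)
    }
  } else {
    params[[paste0(prefix, ".b1")]] <- rep(0, cout)
    params[[paste0(prefix, ".b2")]] <- rep(0, cout)
  }
  params
}

dc_state_init <- function(state, prefix, cout, bn) {
  if (bn) {
    for (nm in c("bn1", "bn2")) {
      state[[paste0(prefix, ".", nm, ".m")]] <- rep(0, cout)
      state[[paste0(prefix, ".", nm, ".v")]] <- rep(1, cout)
    }
  }
  state
}

dc_forward <- function(p, st, prefix, x, sp, training, bn) {
  nm <- function(s) paste0(prefix, ".", s)
  n <- nrow(x)
  z1 <- conv3_forward(x, p[[nm("W1")]], sp)
  if (bn) {
    b1 <- bn_forward(z1, p[[nm("bn1.g")]], p[[nm("bn1.b")]],
                     st[[nm("bn1.m")]], st[[nm("bn1.v")]], training)
    if (training) { st[[nm("bn1.m")]] <- b1$rm; st[[nm("bn1.v")]] <- b1$rv }
    a1 <- b1$out
  } else a1 <- z1 + rep(p[[nm("b1")]], each = n)
  h1 <- relu(a1)
  z2 <- conv3_forward(h1, p[[nm("W2")]], sp)
  if (bn) {
    b2 <- bn_forward(z2, p[[nm("bn2.g")]], p[[nm("bn2.b")]],
                     st[[nm("bn2.m")]], st[[nm("bn2.v")]], training)
    if (training) { st[[nm("bn2.m")]] <- b2$rm; st[[nm("bn2.v")]] <- b2$rv }
    a2 <- b2$out
  } else a2 <- z2 + rep(p[[nm("b2")]], each = n)
  out <- relu(a2)
  list(out = out,
       cache = list(x = x, a1 = a1, h1 = h1, a2 = a2, sp = sp,
                    bn1 = if (bn) b1[c("xhat", "inv")],
                    bn2 = if (bn) b2[c("xhat", "inv")]))
}

dc_backward <- function(p, prefix, cache, dout, grads, bn) {
  nm <- function(s) paste0(prefix, ".", s)
  sp <- cache$sp
  da2 <- relu_grad_cpp(cache$a2, dout)
  if (bn) {
    g2 <- bn_backward(cache$bn2, p[[nm("bn2.g")]], da2)
    grads[[nm("bn2.g")]] <- g2$dg; grads[[nm("bn2.b")]] <- g2$db
    dz2 <- g2$dx
  } else {
    grads[[nm("b2")]] <- colSums(da2)
    dz2 <- da2
  }
  c2 <- conv3_backward(cache$h1, p[[nm("W2")]], sp, dz2)
  grads[[nm("W2")]] <- c2$dW
  da1 <- relu_grad_cpp(cache$a1, c2$dx)
  if (bn) {
    g1 <- bn_backward(cache$bn1, p[[nm("bn1.g")]], da1)
    grads[[nm("bn1.g")]] <- g1$dg; grads[[nm("bn1.b")]] <- g1$db
    dz1 <- g1$dx
  } else {
    grads[[nm("b1")]] <- colSums(da1)
    dz1 <- da1
  }
  c1 <- conv3_backward(cache$x, p[[nm("W1")]], sp, dz1)
  grads[[nm("W1")]] <- c1$dW
  list(dx = c1$dx, grads = grads)
}

upconv_init <- function(params, prefix, cin, cout, rng) {
  params[[paste0(prefix, ".W")]] <-
    matrix(rng_rnorm(rng, cin * 4 * cout, 0, sqrt(2 / cin)), cin, 4 * cout)
  params[[paste0(prefix, ".b")]] <- rep(0, cout)
  params
}

upconv_forward <- function(p, prefix, x, sp) {
  z <- x %*% p[[paste0(prefix, ".W")]]
  out <- depth2space2(z, sp[1], sp[2], sp[3])
  out + rep(p[[paste0(prefix, ".b")]], each = nrow(out))
}

upconv_backward <- function(p, prefix, x, sp, dout, grads) {
  dz <- space2depth2(dout, sp[1], sp[2], sp[3])
  grads[[paste0(prefix, ".W")]] <- crossprod(x, dz)
  grads[[paste0(prefix, ".b")]] <- colSums(dout)
  list(dx = dz %*% t(p[[paste0(prefix, ".W")]]), grads = grads)
}

softmax_rows <- function(z) {
  mx <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) mx <- pmax(mx, z[, j])
  e <- exp(z - mx)
  e / rowSums(e)
}
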