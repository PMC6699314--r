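# Independent scalar oracles: explicit double loops over classes k and
# pixels m, written without reference to the vectorized implementations.

oracle_gdl <- function(Y, T) {
  K <- nrow(Y); M <- ncol(Y)
  w <- numeric(K)
  for (k in 1:K) {
    s <- 0
    for (m in 1:M) s <- s + T[k, m]
    w[k] <- 1 / s^2
  }
  num <- 0; den <- 0
  for (k in 1:K) {
    for (m in 1:M) {
      num <- num + w[k] * Y[k, m] * T[k, m]
      den <- den + w[k] * (Y[k, m]^2 + T[k, m]^2)
    }
  }
  1 - 2 * num / den
}

oracle_igd <- function(Y, T, eps = 1e-8) {
  K <- nrow(Y); M <- ncol(Y)
  w <- numeric(K)
  for (k in 1:K) {
    st <- 0; sy <- 0
    for (m in 1:M) {
      st <- st + T[k, m]
      sy <- sy + Y[k, m]
    }
    w[k] <- if (st > 0) 1 / st else 1 / (sy + eps)
  }
  num <- eps; den <- eps
  for (k in 1:K) {
    for (m in 1:M) {
      num <- num + w[k] * Y[k, m] * T[k, m]
      den <- den + w[k] * (Y[k, m]^2 + T[k, m]^2)
    }
  }
  1 - 2 * num / den
}

oracle_ce <- function(Y, T, floor = 1e-12) {
  K <- nrow(Y); M <- ncol(Y)
  tot <- 0
  for (m in 1:M) {
    for (k in 1:K) {
      tot <- tot - T[k, m] * log(Y[k, m] + floor)
    }
  }
  tot / M
}

# Random (Y, T) instance on the probability simplex; `absent` lists classes
# removed from the ground truth.
random_instance <- function(K = 4, M = 64, absent = NULL) {
  Y <- matrix(runif(K * M), K, M)
  Y <- sweep(Y, 2, colSums(Y), "/")
  lab <- sample(setdiff(1:K, absent), M, replace = TRUE)
  T <- matrix(0, K, M)
  T[cbind(lab, 1:M)] <- 1
  list(Y = Y, T = T)
}

# Direct O(K^2) 3x3 convolution oracle on a tiny grid, zero padding.
oracle_conv3 <- function(img_list, W_array) {
  # img_list: list of H x W input-channel matrices; W_array: array
  # [3, 3, Cin, Cout] with kernel index [dy+2, dx+2]
  H <- nrow(img_list[[1]]); Wd <- ncol(img_list[[1]])
  Cin <- length(img_list); Cout <- dim(W_array)[4]
  out <- vector("list", Cout)
  for (co in 1:Cout) {
    o <- matrix(0, H, Wd)
    for (h in 1:H) for (w in 1:Wd) {
      acc <- 0
      for (ci in 1:Cin) for (dy in -1:1) for (dx in -1:1) {
        hh <- h + dy; ww <- w + dx
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= Wd)
          acc <- acc + img_list[[ci]][hh, ww] * W_array[dy + 2, dx + 2, ci, co]
      }
      o[h, w] <- acc
    }
    out[[co]] <- o
  }
  out
}
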