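test_that("one-hot encoding is a bijection with unit column sums", {
  lab <- label_map(matrix(c(1L, 3L, 4L, 1L, 2L, 2L), 2, 3))
  T <- one_hot_encode(lab, 4)
  expect_equal(dim(T), c(4L, 6L))
  expect_true(all(colSums(T) == 1))
  expect_equal(apply(T, 2, which.max), as.integer(lab))
  allbg <- one_hot_encode(label_map(matrix(1L, 2, 2)), 4)
  expect_true(all(allbg[1, ] == 1) && all(allbg[2:4, ] == 0))
  expect_error(one_hot_encode(matrix(5L, 2, 2), 4), "1..K")
})

test_that("generalized-Dice weights: inverse-square size, infinite when absent", {
  T <- matrix(0, 4, 200)
  T[1, 1:100] <- 1   # 100 pixels
  T[2, 101:150] <- 1 # 50 pixels
  T[3, 151:200] <- 1 # 50 pixels: class 4 absent
  w <- gdl_weights(T)
  expect_equal(w[1], 1e-4)
  expect_equal(w[2], w[3]) # equal sizes, equal weights
  expect_identical(w[4], Inf)
})

test_that("improved weights are finite and follow the present/absent rule", {
  T <- matrix(0, 4, 100)
  T[1, 1:50] <- 1
  T[2, 51:100] <- 1 # classes 3, 4 absent
  Y <- matrix(0.025, 4, 100)
  Y[3, ] <- 0.1 # total predicted mass 10 on absent class 3
  Y[1, ] <- 1 - colSums(Y[2:4, , drop = FALSE])
  w <- igd_weights(Y, T)
  expect_equal(w[1], 1 / 50)
  expect_equal(w[2], 0.02)
  expect_equal(w[3], 1 / (10 + 1e-8))
  expect_true(all(is.finite(w)))
})

test_that("Dice-family losses hit their closed-form endpoints", {
  set.seed(5)
  inst <- random_instance(4, 32)
  # perfect prediction -> 0
  expect_lt(abs(generalized_dice_loss(inst$T, inst$T)), 1e-9)
  expect_lt(improved_generalized_dice_loss(inst$T, inst$T), 1e-6)
  # disjoint one-hot prediction -> 1 (all classes present in T)
  lab_t <- rep(1:4, each = 8)
  lab_y <- c(rep(2:4, each = 8), rep(1, 8)) # never matches
  T <- matrix(0, 4, 32); T[cbind(lab_t, 1:32)] <- 1
  Y <- matrix(0, 4, 32); Y[cbind(lab_y, 1:32)] <- 1
  expect_lt(abs(generalized_dice_loss(Y, T) - 1), 1e-9)
  # uniform prediction: finite, interior
  U <- matrix(0.25, 4, 32)
  l <- improved_generalized_dice_loss(U, T)
  expect_true(is.finite(l) && l > 0 && l < 1)
  # absent class aborts the baseline loss
  T2 <- T; T2[1, ] <- 0; T2[2, T[1, ] == 1] <- 1
  expect_error(generalized_dice_loss(Y, T2), "absent")
})

test_that("losses match the double-loop oracles on random instances", {
  set.seed(77)
  for (i in 1:25) {
    inst <- random_instance(4, 64)
    expect_lt(abs(generalized_dice_loss(inst$Y, inst$T) -
                    oracle_gdl(inst$Y, inst$T)), 1e-10)
    expect_lt(abs(improved_generalized_dice_loss(inst$Y, inst$T) -
                    oracle_igd(inst$Y, inst$T)), 1e-10)
    expect_lt(abs(cross_entropy_loss(inst$Y, inst$T) -
                    oracle_ce(inst$Y, inst$T)), 1e-10)
    absent <- sample(2:4, 1)
    inst2 <- random_instance(4, 64, absent = absent)
    expect_lt(abs(improved_generalized_dice_loss(inst2$Y, inst2$T) -
                    oracle_igd(inst2$Y, inst2$T)), 1e-10)
  }
})

test_that("cross-entropy of a uniform prediction is ln 4", {
  set.seed(8)
  inst <- random_instance(4, 50)
  U <- matrix(0.25, 4, 50)
  expect_equal(cross_entropy_loss(U, inst$T), log(4), tolerance = 1e-9)
  expect_lt(cross_entropy_loss(inst$T, inst$T), 1e-9)
})

test_that("improved loss stays in [0,1] and is permutation-invariant", {
  set.seed(9)
  for (i in 1:20) {
    inst <- random_instance(4, 40, absent = if (i %% 2) 3 else NULL)
    l <- improved_generalized_dice_loss(inst$Y, inst$T)
    expect_gte(l, -1e-6)
    expect_lte(l, 1 + 1e-6)
    perm <- sample(4)
    expect_equal(improved_generalized_dice_loss(inst$Y[perm, ], inst$T[perm, ]),
                 l, tolerance = 1e-12)
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(11)
  fd <- function(f, Y, h = 1e-6) {
    G <- Y * 0
    for (i in seq_along(Y)) {
      Yp <- Y; Ym <- Y
      Yp[i] <- Yp[i] + h; Ym[i] <- Ym[i] - h
      G[i] <- (f(Yp) - f(Ym)) / (2 * h)
    }
    G
  }
  inst <- random_instance(4, 12)
  expect_lt(max(abs(improved_gdl_grad(inst$Y, inst$T) -
                      fd(function(Y) improved_generalized_dice_loss(Y, inst$T),
                         inst$Y))), 1e-8)
  expect_lt(max(abs(gdl_grad(inst$Y, inst$T) -
                      fd(function(Y) generalized_dice_loss(Y, inst$T),
                         inst$Y))), 1e-8)
  inst2 <- random_instance(4, 12, absent = 2)
  g2 <- improved_gdl_grad(inst2$Y, inst2$T)
  expect_true(all(is.finite(g2)))
  expect_lt(max(abs(g2 -
                      fd(function(Y) improved_generalized_dice_loss(Y, inst2$T),
                         inst2$Y))), 1e-8)
})
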