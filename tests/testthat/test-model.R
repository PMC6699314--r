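test_that("residual block descriptor counts match realized parameters", {
  b <- build_residual_block(1, 24)
  expect_equal(b$conv_params, 5424) # 9*1*24 + 9*24^2 + 1*24
  expect_equal(b$affine_params, 6 * 24)
  # descriptor agrees with the parameters actually realized in a network
  spec <- net_spec(rows = 16, cols = 16, base_width = 24, levels = 1)
  net <- build_network(spec, seed = 1)
  enc1 <- net$params[grep("^enc1\\.", names(net$params))]
  expect_equal(sum(lengths(enc1)), b$total_params)
  # additivity: block totals plus head and upconv terms give the network
  blocks <- b$total_params +                        # encoder 1 -> 24
    build_residual_block(24, 48)$total_params +     # bottleneck
    build_residual_block(48, 24)$total_params       # decoder (concat 24+24)
  upconv <- 48 * 4 * 24 + 24
  head <- 24 * 4 + 4
  expect_equal(count_parameters(net), blocks + upconv + head)
})

test_that("residual block parameter count matches the closed form", {
  # (cin=1, cout=24): 9*1*24 + 9*24^2 + 1*24 conv weights + 3 BN pairs
  spec <- net_spec(rows = 16, cols = 16, base_width = 24, levels = 1)
  net <- build_network(spec, seed = 1)
  blk <- net$params[grep("^enc1\\.", names(net$params))]
  conv_n <- sum(lengths(blk[grep("\\.W", names(blk))]))
  expect_equal(conv_n, 9 * 1 * 24 + 9 * 24^2 + 1 * 24) # 5424
  bn_n <- sum(lengths(blk[grep("\\.bn", names(blk))]))
  expect_equal(bn_n, 6 * 24)
})

test_that("tiny network parameter count equals an independent hand count", {
  spec <- net_spec(rows = 8, cols = 8, base_width = 1, levels = 1,
                   classes = 2, growth = 2)
  net <- build_network(spec, seed = 1)
  rb <- function(ci, co) 9 * ci * co + 9 * co^2 + ci * co + 6 * co
  hand <- rb(1, 1) +            # encoder block 1->1
    rb(1, 2) +                  # bottleneck 1->2
    (2 * 4 * 1 + 1) +           # upconv 2->1 (2x2 kernel) + bias
    rb(2, 1) +                  # decoder block (concat 1+1 -> 1)
    (1 * 2 + 2)                 # 1x1 head + bias
  expect_equal(count_parameters(net), hand)
  expect_equal(sum(vapply(summary(net)$n, identity, integer(1))),
               count_parameters(net))
})

test_that("default architecture totals about 4.4 million parameters", {
  net <- build_network(net_spec())
  expect_equal(count_parameters(net) / 1e6, 4.4, tolerance = 0.05)
})

test_that("a single 1x1 head from 24 channels to 4 classes has 100 parameters", {
  net <- build_network(net_spec())
  expect_equal(length(net$params$head.W) + length(net$params$head.b), 100L)
})

test_that("doubling the base width scales the total by about four", {
  n1 <- count_parameters(build_network(net_spec(rows = 32, cols = 32,
                                                base_width = 8, levels = 2)))
  n2 <- count_parameters(build_network(net_spec(rows = 32, cols = 32,
                                                base_width = 16, levels = 2)))
  expect_equal(n2 / n1, 4, tolerance = 0.1)
})

test_that("forward pass keeps spatial shape and produces a SoftMax simplex", {
  spec <- net_spec(rows = 32, cols = 32, base_width = 4, levels = 2)
  net <- build_network(spec, seed = 3)
  x <- matrix(runif(32 * 32 * 2), ncol = 1)
  fw <- net_forward(net, x, n = 2)
  expect_equal(dim(fw$probs), c(32L * 32L * 2L, 4L))
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-6)
  expect_true(all(fw$probs >= 0))
})

test_that("evaluation-mode forward is deterministic", {
  spec <- net_spec(rows = 32, cols = 32, base_width = 4, levels = 2)
  net <- build_network(spec, seed = 3)
  x <- matrix(runif(32 * 32), ncol = 1)
  f1 <- net_forward(net, x)
  f2 <- net_forward(net, x)
  expect_identical(f1$probs, f2$probs)
})

test_that("compiled convolution agrees with a direct sliding-window oracle", {
  set.seed(4)
  H <- 6; W <- 5; Cin <- 2; Cout <- 3
  x <- matrix(rnorm(H * W * Cin), ncol = Cin)
  Wm <- matrix(rnorm(9 * Cin * Cout), 9 * Cin, Cout)
  out <- conv3_fwd_cpp(x, Wm, H, W, 1L)
  # rebuild the kernel as [dy, dx, cin, cout] from the column layout
  Wa <- array(0, c(3, 3, Cin, Cout))
  for (co in 1:Cout) for (ci in 1:Cin) for (dx in -1:1) for (dy in -1:1)
    Wa[dy + 2, dx + 2, ci, co] <-
      Wm[9 * (ci - 1) + (dy + 1) + 3 * (dx + 1) + 1, co]
  imgs <- lapply(1:Cin, function(ci) matrix(x[, ci], H, W))
  oracle <- oracle_conv3(imgs, Wa)
  for (co in 1:Cout)
    expect_lt(max(abs(matrix(out[, co], H, W) - oracle[[co]])), 1e-12)
})

test_that("network backprop matches finite differences through BN and pooling", {
  set.seed(7)
  spec <- net_spec(rows = 16, cols = 16, base_width = 3, levels = 2,
                   dropout = 0)
  net <- build_network(spec, seed = 2)
  n <- 2
  x <- matrix(runif(16 * 16 * n), ncol = 1)
  labs <- list(label_map(matrix(sample(1:4, 256, TRUE), 16, 16)),
               label_map(matrix(sample(c(1L, 3L, 4L), 256, TRUE), 16, 16)))
  loss_of <- function(params) {
    nn <- net; nn$params <- params
    fw <- net_forward(nn, x, n = n, training = TRUE)
    tot <- 0
    for (i in 1:n) {
      ri <- (i - 1) * 256 + 1:256
      tot <- tot + improved_generalized_dice_loss(
        t(fw$probs[ri, , drop = FALSE]), one_hot_encode(labs[[i]], 4))
    }
    tot / n
  }
  fw <- net_forward(net, x, n = n, training = TRUE)
  dprobs <- matrix(0, nrow(fw$probs), 4)
  for (i in 1:n) {
    ri <- (i - 1) * 256 + 1:256
    dprobs[ri, ] <- t(improved_gdl_grad(t(fw$probs[ri, , drop = FALSE]),
                                        one_hot_encode(labs[[i]], 4))) / n
  }
  dlogits <- fw$probs * (dprobs - rowSums(dprobs * fw$probs))
  grads <- net_backward(net, fw$cache, dlogits)
  h <- 1e-5
  for (nm in c("enc1.Wa", "enc2.bnB.g", "bottom.Ws", "dec1.up.W",
               "dec2.block.Wb", "head.W", "head.b")) {
    a <- net$params[[nm]]
    for (j in sample(length(a), 2)) {
      pp <- net$params; pp[[nm]][j] <- pp[[nm]][j] + h
      pm <- net$params; pm[[nm]][j] <- pm[[nm]][j] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_lt(abs(num - grads[[nm]][j]) /
                  max(1e-6, abs(num), abs(grads[[nm]][j])), 1e-4)
    }
  }
})

test_that("encoder halves the grid per level down to 10x8 at the bottleneck", {
  net <- build_network(net_spec()) # 160x128, 4 levels
  x <- matrix(runif(160 * 128), ncol = 1)
  fw <- net_forward(net, x)
  expect_equal(nrow(fw$cache$bottom$x), 10L * 8L)
  expect_error(net_spec(rows = 100, cols = 128, levels = 4), "divisible")
})

test_that("U-Net baseline counts about 31 million parameters at 64 filters", {
  un <- build_unet_baseline(64)
  expect_gt(count_parameters(un), 2.5e7)
  expect_lt(count_parameters(un), 3.5e7)
})

test_that("tiny U-Net parameter count equals an independent hand count", {
  un <- build_unet_baseline(1, classes = 2, rows = 8, cols = 8, levels = 1)
  dc <- function(ci, co) 9 * ci * co + 9 * co^2 + 4 * co
  hand <- dc(1, 1) + dc(1, 2) + (2 * 4 * 1 + 1) + dc(2, 1) + (1 * 2 + 2)
  expect_equal(count_parameters(un), hand)
  # forward contract identical to the residual network
  x <- matrix(runif(8 * 8), ncol = 1)
  fw <- net_forward(un, x)
  expect_equal(dim(fw$probs), c(64L, 2L))
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-6)
})

test_that("predict maps probabilities to labels with ties toward lower labels", {
  spec <- net_spec(rows = 16, cols = 16, base_width = 2, levels = 1)
  net <- build_network(spec, seed = 5)
  lab <- predict(net, matrix(runif(16 * 16), 16, 16))
  expect_s3_class(lab, "label_map")
  expect_true(all(as.integer(lab) %in% 1:4))
  expect_error(predict(net, matrix(0, 8, 8)), "expected")
  # tie rule on raw probabilities
  p <- matrix(0.25, 6, 4)
  expect_true(all(max.col(p, ties.method = "first") == 1L))
})

test_that("checkpoints round trip through save/load", {
  net <- build_network(net_spec(rows = 16, cols = 16, base_width = 2,
                                levels = 1), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(net, f)
  back <- load_network(f)
  expect_identical(back$params, net$params)
  x <- matrix(runif(256), 16, 16)
  expect_identical(predict(net, x), predict(back, x))
})
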