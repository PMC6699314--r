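# Small in-memory phantom dataset at a reduced grid for fast training tests.
tiny_data <- function(n, seed, rows = 32, cols = 32, mode = "mix") {
  cfg <- phantom_config(rows = rows, cols = cols, lv_radius = 6,
                        myo_thickness = 3, rv_offset = 7, rv_thickness = 4,
                        shift = c(0, 0))
  rng <- rng_new(seed)
  modes <- if (mode == "mix")
    rng_sample(rng, c("apex", "mid", "mid", "base"), n, replace = TRUE)
  else rep(mode, n)
  phases <- rng_sample(rng, c("ED", "ES"), n, replace = TRUE)
  seeds <- floor(rng_runif(rng, n, 0, 2^31 - 1))
  imgs <- list(); labs <- list()
  pre <- preprocess_config(rows = rows, cols = cols, clahe_tiles = c(4, 4))
  for (i in seq_len(n)) {
    c2 <- cfg; c2$slice_mode <- modes[i]
    sh <- round(rng_runif(rng, 2, -2, 2))
    c2$shift <- sh
    ph <- generate_phantom(c2, seed = seeds[i], phase = phases[i])
    imgs[[i]] <- unclass(preprocess_pipeline(ph$image, pre))[, ]
    labs[[i]] <- ph$label
  }
  list(images = imgs, labels = labs)
}

test_that("learning-rate schedule decays, restarts and is periodic", {
  cfg <- train_config()
  expect_equal(lr_schedule(1, cfg), 1e-3)
  expect_equal(lr_schedule(2, cfg), 9.8e-4)
  expect_equal(lr_schedule(101, cfg), 1e-3)
  e <- 1:300
  lr <- lr_schedule(e, cfg)
  expect_equal(lr[e], lr[((e - 1) %% 100) + 1]) # periodic
  within <- lr[1:100]
  expect_true(all(diff(within) < 0)) # strictly decreasing within a period
  expect_equal(lr[50], 1e-3 * 0.98^49)
})

test_that("images_seen implements drop-last accounting (377,600 at paper scale)", {
  expect_equal(images_seen(16, 16, 1), 16)
  expect_equal(images_seen(17, 16, 2), 32)
  expect_equal(images_seen(1902, 16, 200), 377600)
  expect_gte(images_seen(1902, 16, 200), 377000)
})

test_that("moving-average smoothing has the stated edge behavior", {
  h <- data.frame(epoch = 1:3, lr = 1, train_loss = c(0, 1, 0),
                  train_dice = c(1, 1, 1), valid_loss = c(2, 4, 6),
                  valid_dice = c(0.1, 0.2, 0.3))
  expect_identical(smooth_history(h, 1), h)
  s <- smooth_history(h, 3)
  expect_equal(s$train_loss, c(0.5, 1 / 3, 0.5))
  expect_equal(s$train_dice, c(1, 1, 1)) # constants unchanged
  expect_equal(s$valid_loss[2], 4)
})

test_that("training is reproducible, logs history, and selects the best model", {
  tr <- tiny_data(8, seed = 100)
  va <- tiny_data(4, seed = 200)
  spec <- net_spec(rows = 32, cols = 32, base_width = 4, levels = 2)
  cfg <- train_config(epochs = 3, minibatch = 4, loss = "igd",
                      augment = TRUE, seed = 5, bn_finalize = FALSE)
  f1 <- train(build_network(spec, seed = 5), tr, va, cfg)
  f2 <- train(build_network(spec, seed = 5), tr, va, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
  expect_equal(nrow(f1$history), 3L)
  expect_true(all(c("epoch", "lr", "train_loss", "train_dice", "valid_loss",
                    "valid_dice") %in% names(f1$history)))
  expect_equal(f1$history$lr, lr_schedule(1:3, cfg))
  # best-model selection: returned weights achieve max validation dice
  expect_equal(evaluate_dataset(f1$net, va)$mean_dice,
               max(f1$history$valid_dice), tolerance = 1e-12)
})

test_that("a zero-epoch request still runs one epoch", {
  tr <- tiny_data(4, seed = 1)
  cfg <- train_config(epochs = 0, minibatch = 4, augment = FALSE, seed = 1)
  fit <- train(build_network(net_spec(rows = 32, cols = 32, base_width = 2,
                                      levels = 1), seed = 1), tr, tr, cfg)
  expect_equal(nrow(fit$history), 1L)
})

test_that("augmented training writes nothing to disk", {
  tr <- tiny_data(8, seed = 7)
  d <- withr::local_tempdir()
  withr::local_dir(d)
  before <- list.files(tempdir(), recursive = TRUE)
  cfg <- train_config(epochs = 2, minibatch = 4, augment = TRUE, seed = 2)
  fit <- train(build_network(net_spec(rows = 32, cols = 32, base_width = 2,
                                      levels = 1), seed = 2), tr, tr, cfg)
  expect_length(list.files(d, recursive = TRUE), 0L)
  expect_identical(list.files(tempdir(), recursive = TRUE), before)
})

test_that("empty validation sets and undersized training sets are rejected", {
  tr <- tiny_data(4, seed = 3)
  none <- list(images = list(), labels = list())
  cfg <- train_config(epochs = 1, minibatch = 4, seed = 1)
  net <- build_network(net_spec(rows = 32, cols = 32, base_width = 2,
                                levels = 1), seed = 1)
  expect_error(train(net, tr, none, cfg), "validation")
  cfg2 <- train_config(epochs = 1, minibatch = 64, seed = 1)
  # minibatch is capped at the training-set size rather than failing
  fit <- train(net, tr, tr, cfg2)
  expect_equal(nrow(fit$history), 1L)
})

test_that("short training improves validation Dice on phantoms", {
  # learning-progress smoke test: majority over 3 seeds
  wins <- 0L
  for (s in 1:3) {
    tr <- tiny_data(16, seed = 300 + s)
    va <- tiny_data(6, seed = 400 + s)
    spec <- net_spec(rows = 32, cols = 32, base_width = 6, levels = 2)
    cfg <- train_config(epochs = 6, minibatch = 8, loss = "igd",
                        augment = FALSE, seed = s)
    fit <- train(build_network(spec, seed = s), tr, va, cfg)
    h <- fit$history
    if (h$valid_dice[nrow(h)] > h$valid_dice[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("batch-norm finalization swaps statistics, not weights", {
  tr <- tiny_data(8, seed = 50)
  cfg <- train_config(epochs = 2, minibatch = 4, augment = FALSE, seed = 4,
                      bn_finalize = FALSE)
  fit <- train(build_network(net_spec(rows = 32, cols = 32, base_width = 4,
                                      levels = 2), seed = 4), tr, tr, cfg)
  fin1 <- finalize_bn_stats(fit$net, tr, 4L)
  fin2 <- finalize_bn_stats(fit$net, tr, 4L)
  expect_identical(fin1$params, fit$net$params)
  expect_identical(fin1$state, fin2$state)
  expect_false(identical(fin1$state, fit$net$state))
  # single-batch dataset: population stats are that batch's moments, so a
  # second finalization starting from them reproduces itself
  one <- list(images = tr$images[1:4], labels = tr$labels[1:4])
  f1 <- finalize_bn_stats(fit$net, one, 4L)
  f2 <- finalize_bn_stats(f1, one, 4L)
  expect_equal(f1$state, f2$state, tolerance = 1e-10)
})

test_that("run_ablation produces one structured row per arm", {
  tr <- tiny_data(8, seed = 21)
  va <- tiny_data(4, seed = 22)
  arms <- data.frame(model = c("residual", "residual"),
                     loss = c("igd", "ce"), augment = c(TRUE, FALSE))
  spec <- net_spec(rows = 32, cols = 32, base_width = 2, levels = 1)
  cfg <- train_config(epochs = 1, minibatch = 4, seed = 3)
  tab <- run_ablation(arms, spec, tr, va, config = cfg)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("model", "loss", "augment", "valid_mean_dice",
                    "valid_dice_k4") %in% names(tab)))
  # identical arms give identical rows under the same seed
  arms2 <- arms[c(1, 1), ]
  tab2 <- run_ablation(arms2, spec, tr, va, config = cfg)
  expect_equal(tab2$valid_mean_dice[1], tab2$valid_mean_dice[2])
})
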