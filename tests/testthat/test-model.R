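test_that("separable convolutions need far fewer parameters than standard ones", {
  expect_identical(separable_conv_params(3, 32, 64), 3 * 3 * 32 + 32 * 64)
  expect_identical(separable_conv_params(3, 32, 64), 2336)
  expect_identical(standard_conv_params(3, 32, 64), 18432)
  for (Dk in 2:5) for (M in c(1, 8, 32)) for (N in c(2, 16, 64))
    expect_lt(separable_conv_params(Dk, M, N), standard_conv_params(Dk, M, N))
})

test_that("count_parameters equals the closed-form sum for a grid of configs", {
  grid <- list(
    tiny_ppgnet_config(use_bn = TRUE),
    tiny_ppgnet_config(use_bn = FALSE),
    ppgnet_config(input_size = c(32L, 32L, 3L), stem_widths = c(4L, 8L),
                  entry_widths = c(8L, 12L), middle_blocks = 2L,
                  middle_width = 12L, exit_widths = c(16L, 20L)),
    reduced_ppgnet_config(64L)
  )
  for (cfg in grid) {
    m <- build_ppgnet(cfg, seed = 1)
    pc <- count_parameters(m)
    oracle <- closed_form_counts(cfg)
    expect_identical(as.integer(pc), as.integer(oracle$main))
    expect_identical(as.integer(attr(pc, "bn_params")), as.integer(oracle$bn))
  }
})

test_that("adding middle blocks adds exactly the per-block parameter count", {
  base <- ppgnet_config(input_size = c(32L, 32L, 3L), stem_widths = c(4L, 8L),
                        entry_widths = c(8L), middle_blocks = 1L,
                        middle_width = 8L, exit_widths = c(12L))
  more <- base; more$middle_blocks <- 3L
  d <- count_parameters(build_ppgnet(more, 1)) - count_parameters(build_ppgnet(base, 1))
  per_block <- 3 * (9 * 8 + 8 * 8)    # three separable convs at width 8, no bias
  expect_identical(as.integer(d), as.integer(2L * per_block))
})

test_that("forward passes produce probability vectors and per-image labels", {
  cfg <- tiny_ppgnet_config()
  m <- build_ppgnet(cfg, seed = 2)
  imgs <- rand_images(5)
  pred <- predict_ppgnet(m, imgs)
  expect_identical(dim(pred$probabilities), c(5L, 4L))
  expect_true(all(pred$probabilities >= 0))
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, 5), tolerance = 1e-6)
  expect_identical(length(pred$labels), 5L)
  expect_identical(pred$stage, label_decode(pred$labels))

  # exact tie at the argmax resolves to the lowest class index
  m0 <- m
  m0$weights$dense_W[] <- 0
  m0$weights$dense_b[] <- 0
  tie <- predict_ppgnet(m0, imgs[1])
  expect_equal(unname(tie$probabilities[1, ]), rep(0.25, 4), tolerance = 1e-12)
  expect_identical(tie$labels, 0L)
})

test_that("backpropagation matches finite differences (BN off)", {
  cfg <- tiny_ppgnet_config(use_bn = FALSE)
  m <- build_ppgnet(cfg, seed = 3)
  imgs <- rand_images(6, seed = 9)
  y <- c(0L, 1L, 2L, 3L, 0L, 1L)
  X <- ppgnet:::stack_images(imgs)
  loss_fn <- function(w) {
    p <- ppgnet:::cpp_predict(unclass(cfg), w, X)
    -mean(log(pmax(p[cbind(1:6, y + 1)], 1e-12)))
  }
  lr <- 1e-6
  fit <- ppgnet:::cpp_train(unclass(cfg), m$weights, X, y, 0:5, integer(0),
                            list(learning_rate = lr, momentum = 0, batch_size = 6L,
                                 epochs = 1L, early_stop_patience = 5L,
                                 seed = 1L, verbose = FALSE))
  withr::with_seed(42, {
    for (trial in 1:10) {
      nm <- sample(names(m$weights), 1)
      k <- sample(length(m$weights[[nm]]), 1)
      ga <- (m$weights[[nm]][k] - fit$weights[[nm]][k]) / lr
      eps <- 1e-5
      wp <- m$weights; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- m$weights; wm[[nm]][k] <- wm[[nm]][k] - eps
      gn <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
      expect_lt(abs(ga - gn) / max(abs(ga), abs(gn), 1e-6), 1e-3)
    }
  })
})

test_that("backpropagation matches finite differences through batch norm", {
  cfg <- tiny_ppgnet_config(use_bn = TRUE)
  m <- build_ppgnet(cfg, seed = 3)
  imgs <- rand_images(6, seed = 10)
  y <- c(0L, 1L, 2L, 3L, 0L, 1L)
  X <- ppgnet:::stack_images(imgs)
  # lr = 0 probe: the first-epoch full-batch loss is the train-mode loss at w
  train_loss <- function(w) ppgnet:::cpp_train(
    unclass(cfg), w, X, y, 0:5, integer(0),
    list(learning_rate = 0, momentum = 0, batch_size = 6L, epochs = 1L,
         early_stop_patience = 5L, seed = 1L, verbose = FALSE))$history$loss[1]
  lr <- 1e-6
  fit <- ppgnet:::cpp_train(unclass(cfg), m$weights, X, y, 0:5, integer(0),
                            list(learning_rate = lr, momentum = 0, batch_size = 6L,
                                 epochs = 1L, early_stop_patience = 5L,
                                 seed = 1L, verbose = FALSE))
  withr::with_seed(43, {
    for (trial in 1:10) {
      nm <- sample(grep("rmean|rvar", names(m$weights), invert = TRUE, value = TRUE), 1)
      k <- sample(length(m$weights[[nm]]), 1)
      ga <- (m$weights[[nm]][k] - fit$weights[[nm]][k]) / lr
      eps <- 1e-5
      wp <- m$weights; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- m$weights; wm[[nm]][k] <- wm[[nm]][k] - eps
      gn <- (train_loss(wp) - train_loss(wm)) / (2 * eps)
      expect_lt(abs(ga - gn) / max(abs(ga), abs(gn), 1e-6), 1e-3)
    }
  })
})

test_that("training reduces the loss and is deterministic given the seed", {
  cfg <- tiny_ppgnet_config()
  m <- build_ppgnet(cfg, seed = 4)
  # two visually distinct synthetic "classes": bright top half vs bottom half
  imgs <- withr::with_seed(20, c(
    lapply(1:6, function(i) { a <- array(runif(16 * 16 * 2) * 40, c(16, 16, 2)); a[1:8, , ] <- a[1:8, , ] + 180; a }),
    lapply(1:6, function(i) { a <- array(runif(16 * 16 * 2) * 40, c(16, 16, 2)); a[9:16, , ] <- a[9:16, , ] + 180; a })))
  y <- rep(c(0L, 1L), each = 6)
  tc <- train_config(epochs = 8L, batch_size = 4L, early_stop_patience = 8L, seed = 6)
  fit <- train_ppgnet(m, imgs, y, train_idx = 1:12, val_idx = 1:12, tc)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  fit2 <- train_ppgnet(m, imgs, y, train_idx = 1:12, val_idx = 1:12, tc)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)
})

test_that("early stopping halts on a plateau and keeps the best epoch's weights", {
  cfg <- tiny_ppgnet_config()
  m <- build_ppgnet(cfg, seed = 5)
  imgs <- rand_images(8, seed = 21)
  y <- rep(0:3, 2)
  # near-zero learning rate: accuracy cannot improve, so the plateau rule fires
  tc <- train_config(learning_rate = 1e-8, epochs = 15L, batch_size = 4L,
                     early_stop_patience = 3L, seed = 7)
  fit <- train_ppgnet(m, imgs, y, train_idx = 1:6, val_idx = 7:8, tc)
  expect_lt(fit$stopped_epoch, 15L)
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  # returned weights reproduce the recorded best validation accuracy
  pred <- predict_ppgnet(fit, imgs[7:8])
  expect_equal(mean(pred$labels == y[7:8]), fit$best_val_accuracy)
})

test_that("training rejects inconsistent inputs", {
  cfg <- tiny_ppgnet_config()
  m <- build_ppgnet(cfg, seed = 6)
  imgs <- rand_images(4, seed = 22)
  tc <- train_config(epochs = 1L)
  expect_error(train_ppgnet(m, imgs, rep(0L, 4), integer(0), 1:2, tc), "empty")
  expect_error(train_ppgnet(m, imgs, c(0L, 9L, 1L, 2L), 1:4, integer(0), tc))
  bad <- rand_images(1, hw = 8L)
  expect_error(predict_ppgnet(m, bad))
})
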