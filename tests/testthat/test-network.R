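test_that("depthwise convolution matches the loop oracle and identities", {
  set.seed(5)
  # identity kernel
  x <- matrix(rnorm(3 * 8), 3, 8)
  id <- matrix(rep(c(0, 1, 0), each = 3), 3, 3)
  expect_equal(depthwise_conv1d(x, id), x)
  # random instances vs brute force
  for (i in 1:20) {
    M <- sample(1:4, 1); L <- sample(4:16, 1); dk <- sample(c(1, 3, 5), 1)
    xx <- matrix(rnorm(M * L), M, L)
    ww <- matrix(rnorm(M * dk), M, dk)
    expect_equal(depthwise_conv1d(xx, ww), brute_depthwise(xx, ww),
                 tolerance = 1e-12)
  }
  # single channel equals ordinary 1-channel convolution
  x1 <- matrix(rnorm(10), 1, 10)
  w1 <- matrix(rnorm(3), 1, 3)
  expect_equal(depthwise_conv1d(x1, w1), brute_depthwise(x1, w1))
  expect_error(depthwise_conv1d(x, matrix(1, 2, 3)),
               class = "sersquant_shape_error")
  expect_error(depthwise_conv1d(x, matrix(1, 3, 4)),
               class = "sersquant_shape_error")
})

test_that("pointwise convolution is a per-position channel map", {
  set.seed(6)
  x <- matrix(rnorm(3 * 7), 3, 7)
  expect_equal(pointwise_conv1d(x, diag(3)), x)
  w <- matrix(rnorm(2 * 3), 2, 3)
  b <- rnorm(2)
  expect_equal(pointwise_conv1d(x, w, b), brute_pointwise(x, w, b),
               tolerance = 1e-12)
  # all-ones 1xM weights sum the channels
  expect_equal(pointwise_conv1d(x, matrix(1, 1, 3)),
               matrix(colSums(x), 1, 7))
  expect_error(pointwise_conv1d(x, matrix(1, 2, 4)),
               class = "sersquant_shape_error")
})

test_that("separable convolution composes the two oracles", {
  set.seed(8)
  for (i in 1:10) {
    M <- sample(1:4, 1); N <- sample(1:4, 1)
    L <- sample(4:16, 1); dk <- sample(c(3, 5), 1)
    x <- matrix(rnorm(M * L), M, L)
    kern <- matrix(rnorm(M * dk), M, dk)
    w <- matrix(rnorm(N * M), N, M)
    b <- rnorm(N)
    expect_equal(separable_conv1d(x, kern, w, b),
                 brute_pointwise(brute_depthwise(x, kern), w, b),
                 tolerance = 1e-12)
  }
  # identity composition
  x <- matrix(rnorm(2 * 6), 2, 6)
  id_k <- matrix(rep(c(0, 1, 0), each = 2), 2, 3)
  expect_equal(separable_conv1d(x, id_k, diag(2)), x)
})

test_that("parameter-cost ratio follows the analytic formula", {
  expect_equal(cost_ratio(3, 8), 11 / 24)
  expect_equal(cost_ratio(1, 1), 2)
  expect_equal(cost_ratio(5, 1e9), 1 / 5, tolerance = 1e-8)
  set.seed(9)
  for (i in 1:20) {
    dk <- sample(c(1, 3, 5, 7), 1)
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    expect_equal(separable_param_count(dk, m, n) / standard_param_count(dk, m, n),
                 cost_ratio(dk, n))
  }
  expect_error(cost_ratio(0, 3), class = "sersquant_value_error")
})

test_that("residual block is the identity at zero branch weights", {
  set.seed(10)
  x <- matrix(rnorm(3 * 9), 3, 9)
  blk <- list(dw1 = matrix(0, 3, 3), pw1 = matrix(0, 3, 3), pb1 = rep(0, 3),
              dw2 = matrix(0, 3, 3), pw2 = matrix(0, 3, 3), pb2 = rep(0, 3))
  expect_equal(residual_block(x, blk), x)
  # equals manual F(x) + x with the conv oracles
  blk2 <- list(dw1 = matrix(rnorm(9), 3, 3), pw1 = matrix(rnorm(9), 3, 3),
               pb1 = rnorm(3), dw2 = matrix(rnorm(9), 3, 3),
               pw2 = matrix(rnorm(9), 3, 3), pb2 = rnorm(3))
  a1 <- brute_pointwise(brute_depthwise(x, blk2$dw1), blk2$pw1, blk2$pb1)
  a1[a1 < 0] <- 0
  fx <- brute_pointwise(brute_depthwise(a1, blk2$dw2), blk2$pw2, blk2$pb2)
  expect_equal(residual_block(x, blk2), fx + x, tolerance = 1e-12)
  # channel change without projection is an error
  blk3 <- blk2
  blk3$pw2 <- matrix(rnorm(6), 2, 3)
  blk3$pb2 <- rnorm(2)
  expect_error(residual_block(x, blk3), class = "sersquant_shape_error")
})

test_that("model construction is seeded and counts parameters analytically", {
  cfg <- cnn_config(input_length = 521)
  # stem 7*8+8; block1 8*5+16*8+16+16*5+16*16+16+proj 16*8+16; block2 same
  # without proj; head 16*16+16+16+1
  expect_equal(count_params(cfg), 64 + 680 + 704 + 289)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  expect_length(flatten_weights(m1), count_params(cfg))
  m3 <- build_model(cfg, seed = 99)
  expect_false(identical(m1$params, m3$params))
  # stem + head only still works
  cfg0 <- cnn_config(input_length = 30, n_blocks = 0)
  expect_equal(count_params(cfg0), 64 + (16 * 8 + 16) + 17)
  p0 <- predict(build_model(cfg0), matrix(rnorm(60), 2, 30))
  expect_true(all(is.finite(p0)))
  expect_error(cnn_config(input_length = 10, stem_kernel = 4),
               class = "sersquant_config_error")
})

test_that("prediction is deterministic and batching-invariant", {
  cfg <- cnn_config(input_length = 25, stem_channels = 3, block_channels = 4,
                    hidden = 5, seed = 2)
  m <- build_model(cfg)
  set.seed(20)
  x <- matrix(rnorm(6 * 25), 6, 25)
  p1 <- predict(m, x)
  expect_identical(p1, predict(m, x))
  p_each <- vapply(1:6, function(i) predict(m, x[i, , drop = FALSE]),
                   numeric(1))
  expect_equal(p1, p_each, tolerance = 1e-12)
  expect_true(all(is.finite(p1)))
  expect_error(predict(m, x[, 1:10]), class = "sersquant_shape_error")
})

test_that("backprop gradients match finite differences through the loss", {
  cfg <- cnn_config(input_length = 9, stem_channels = 2, stem_kernel = 3,
                    block_channels = 3, block_kernel = 3, n_blocks = 2,
                    hidden = 4, seed = 5)
  m <- build_model(cfg)
  set.seed(9)
  x <- matrix(rnorm(4 * 9), 4, 9)
  y <- runif(4)
  flat <- flatten_weights(m)
  lossfn <- function(v) {
    kernel_huber(y, predict(unflatten_weights(v, m), x), delta = 0.5,
                 sigma = 0.8)
  }
  fw <- sersquant:::model_forward(m$params, cfg,
                                  sersquant:::spectra_to_input(x),
                                  keep_cache = TRUE)
  dy <- kernel_huber_grad(y, fw$yhat, delta = 0.5, sigma = 0.8,
                          detach_weights = FALSE)
  g <- unlist(sersquant:::model_backward(m$params, cfg, fw$cache, dy),
              use.names = FALSE)
  fd <- fd_gradient(lossfn, flat)
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("training contracts: null step, memorization, loss reduction", {
  cfg <- cnn_config(input_length = 12, stem_channels = 2, block_channels = 3,
                    n_blocks = 1, hidden = 4, seed = 3)
  m <- build_model(cfg)
  set.seed(30)
  x <- matrix(runif(5 * 12), 5, 12)
  y <- runif(5)
  # lr = 0 leaves the weights untouched and the history flat
  t0 <- train_network(m, x, y, lr = 0, epochs = 5)
  expect_identical(t0$model$params, m$params)
  expect_equal(diff(t0$history$loss), rep(0, 4))
  # a single sample is memorised
  t1 <- train_network(m, x[1, , drop = FALSE], y[1], lr = 0.05, epochs = 400)
  expect_lt(t1$history$loss[400], 1e-3)
  # on a small clean learnable problem the loss drops substantially
  y_clean <- 0.2 + 0.6 * rowMeans(x)
  t2 <- train_network(m, x, y_clean, lr = 0.02, epochs = 200)
  expect_lt(t2$history$loss[200], 0.1 * t2$history$loss[1])
  expect_error(train_network(m, x, y, init = rep(0, 3)),
               class = "sersquant_shape_error")
})

test_that("training reduces loss monotonically on clean data for most seeds", {
  monotone <- vapply(1:5, function(s) {
    cfg <- cnn_config(input_length = 10, stem_channels = 2, block_channels = 3,
                      n_blocks = 1, hidden = 4, seed = s)
    m <- build_model(cfg)
    sim <- with_seed_local(s, {
      x <- matrix(runif(6 * 10), 6, 10)
      list(x = x, y = 0.2 + 0.6 * rowMeans(x))
    })
    tr <- train_network(m, sim$x, sim$y, lr = 1e-3, epochs = 40)
    all(diff(tr$history$loss) <= 1e-10)
  }, logical(1))
  expect_gte(sum(monotone), 4)
})

test_that("cosine schedule trains and ends with tiny steps", {
  cfg <- cnn_config(input_length = 10, stem_channels = 2, block_channels = 3,
                    n_blocks = 1, hidden = 4, seed = 7)
  m <- build_model(cfg)
  set.seed(77)
  x <- matrix(runif(6 * 10), 6, 10)
  y <- runif(6)
  tr <- train_network(m, x, y, lr = 0.01, epochs = 50, lr_schedule = "cosine")
  expect_lt(tr$history$loss[50], tr$history$loss[1])
})
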