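test_that("encoder specs validate their hyperparameters", {
  expect_error(encoder_spec(epochs = 0))
  expect_error(encoder_spec(dropout_rate = 1))
  expect_error(encoder_spec(layer_sizes = integer()))
  spec <- encoder_spec(c(64, 32, 32, 16))
  expect_equal(spec$layer_sizes, c(64L, 32L, 32L, 16L))
  expect_equal(spec$optimizer, "adam")
})

test_that("parameter counts follow the layerwise fan-in formula", {
  e1 <- encoder_spec(c(64, 32, 32, 16))
  expect_equal(count_parameters(e1, input_dim = 800, output_dim = 27), 56144L)
  expect_equal(count_parameters(e1, input_dim = 0, output_dim = 27), 4144L)
  e2 <- encoder_spec(c(32, 24, 16))
  expect_equal(count_parameters(e2, input_dim = 16 * 4, output_dim = 27), 3752L)
})

test_that("training reduces the loss on a learnable toy problem", {
  set.seed(1)
  X <- cbind(rnorm(80), rnorm(80))
  y <- matrix(as.numeric(X[, 1] * X[, 2] > 0), ncol = 1) # XOR-style target
  spec <- encoder_spec(c(16, 8), dropout_rate = 0, learning_rate = 5e-3,
                       batch_size = 16, epochs = 200)
  enc <- train_encoder(X, y, spec, seed = 3)
  expect_lt(tail(enc$training_log, 1), enc$training_log[1])
  expect_length(enc$training_log, 200)
})

test_that("a linearly separable set is fit almost perfectly", {
  set.seed(2)
  n <- 100
  X <- cbind(c(rnorm(n / 2, -2), rnorm(n / 2, 2)), rnorm(n))
  y <- matrix(rep(c(0, 1), each = n / 2), ncol = 1)
  # oracle: the problem is separable for a linear classifier
  expect_gt(auroc(lr_baseline(X, y)[, 1], y[, 1]), 0.95)
  spec <- encoder_spec(c(16, 8), dropout_rate = 0, learning_rate = 5e-3,
                       batch_size = 32, epochs = 150)
  enc <- train_encoder(X, y, spec, seed = 4)
  expect_gt(auroc(predict_scores(enc, X)[, 1], y[, 1]), 0.95)
})

test_that("training and prediction are deterministic given the seed", {
  set.seed(9)
  X <- matrix(rnorm(60 * 5), 60, 5)
  Y <- matrix(rbinom(60 * 3, 1, 0.3), 60, 3)
  spec <- encoder_spec(c(8, 4), dropout_rate = 0.5, learning_rate = 1e-3,
                       batch_size = 16, epochs = 20)
  a <- train_encoder(X, Y, spec, seed = 7)
  b <- train_encoder(X, Y, spec, seed = 7)
  expect_identical(a$training_log, b$training_log)
  expect_equal(predict_scores(a, X), predict_scores(b, X), tolerance = 1e-6)
  c2 <- train_encoder(X, Y, spec, seed = 8)
  expect_false(identical(a$training_log, c2$training_log))
  # dropout is inactive at inference: repeated prediction identical
  expect_identical(predict_scores(a, X), predict_scores(a, X))
})

test_that("scores live in [0, 1] and a zero-weight model is constant", {
  set.seed(11)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- matrix(rbinom(30 * 2, 1, 0.5), 30, 2)
  enc <- train_encoder(X, Y, encoder_spec(c(6), dropout_rate = 0, epochs = 5,
                                          learning_rate = 1e-3, batch_size = 8),
                       seed = 1)
  S <- predict_scores(enc, X)
  expect_true(all(S >= 0 & S <= 1))
  # zero all weights: every gene scores (tanh(bias) + 1) / 2
  enc$layers <- lapply(enc$layers, function(l) list(W = l$W * 0, b = l$b * 0 + 0.3))
  S0 <- predict_scores(enc, X)
  hidden_out <- 0.3 # relu(0 + 0.3)
  expect_equal(unique(round(as.vector(S0), 12)),
               round((tanh(hidden_out * 0 + 0.3) + 1) / 2, 12))
})

test_that("bottlenecks are the last hidden layer: width, determinism, sign", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- matrix(rbinom(40 * 27, 1, 0.2), 40, 27)
  spec <- encoder_spec(c(64, 32, 32, 16), dropout_rate = 0.5,
                       learning_rate = 1e-3, batch_size = 16, epochs = 5)
  enc <- train_encoder(X, Y, spec, seed = 2)
  bn <- extract_bottleneck(enc, X)
  expect_equal(ncol(bn$matrix), 16)
  expect_true(all(bn$matrix >= 0)) # rectifier output
  # identical input rows give identical bottleneck rows
  X2 <- rbind(X[1, ], X[1, ])
  bn2 <- extract_bottleneck(enc, X2)
  expect_equal(bn2$matrix[1, ], bn2$matrix[2, ])
  # all-zero input row passes only through the bias cascade
  bz <- extract_bottleneck(enc, matrix(0, 2, 6))
  expect_equal(bz$matrix[1, ], bz$matrix[2, ])
  expect_error(extract_bottleneck(enc, matrix(0, 2, 5)), "does not match")
})

test_that("bottleneck concatenation preserves order and total width", {
  mk <- function(name, n = 5, w = 16) {
    structure(list(matrix = matrix(seq_len(n * w), n, w,
                                   dimnames = list(paste0("g", 1:n), NULL)),
                   source = name),
              class = "bottleneck_features")
  }
  expect_equal(ncol(concatenate_bottlenecks(lapply(1:4, mk))), 64)
  expect_equal(ncol(concatenate_bottlenecks(lapply(1:5, mk))), 80)
  one <- mk("solo")
  expect_equal(unname(concatenate_bottlenecks(list(one))), unname(one$matrix))
  bad <- mk("bad")
  rownames(bad$matrix) <- rev(rownames(bad$matrix))
  expect_error(concatenate_bottlenecks(list(mk("a"), bad)), "mismatch")
})

test_that("empty or misaligned training input is rejected", {
  expect_error(train_encoder(matrix(numeric(), 0, 2), matrix(numeric(), 0, 1),
                             encoder_spec(c(4), epochs = 1)))
  expect_error(train_encoder(matrix(0, 3, 2), matrix(0, 4, 1),
                             encoder_spec(c(4), epochs = 1)))
})

test_that("the two-stage model is reproducible and scores all labels", {
  set.seed(20)
  X1 <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(paste0("g", 1:50), NULL))
  X2 <- matrix(rbinom(50 * 4, 1, 0.3), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
  Y <- matrix(rbinom(50 * 3, 1, 0.4), 50, 3)
  cfg <- benchmark_config(seeds = 1, epochs = 10)
  m1 <- fit_mdl(list(X1, X2), Y, cfg, seed = 5)
  m2 <- fit_mdl(list(X1, X2), Y, cfg, seed = 5)
  s1 <- predict(m1, list(X1, X2))
  expect_equal(s1, predict(m2, list(X1, X2)), tolerance = 1e-6)
  expect_equal(dim(s1), c(50L, 3L))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_length(m1$encoders, 2)
})
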