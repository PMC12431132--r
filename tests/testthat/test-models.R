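# CNN engine: architecture, parameter counts, gradients, training behaviour.

test_that("filter ladder keeps the canonical two-block pair", {
  expect_identical(cnn_filter_ladder(2), c(16L, 64L))
  expect_identical(cnn_filter_ladder(3), c(16L, 32L, 64L))
  expect_identical(cnn_filter_ladder(5), c(16L, 32L, 64L, 128L, 128L))
})

test_that("parameter count matches the closed form for the 2-block model", {
  model <- build_cnn(cnn_config())   # 64x64x3 input, filters (16, 64)
  # conv1: 3*3*3*16 + 16; conv2: 3*3*16*64 + 64;
  # flatten: 16*16*64 = 16384 -> dense 128; head 128 -> 1
  expected <- (3 * 3 * 3 * 16 + 16) + (3 * 3 * 16 * 64 + 64) +
    (16384 * 128 + 128) + (128 + 1)
  expect_equal(n_parameters(model), expected)
  # 'same' padding keeps spatial size through conv; pooling halves it
  flat_layer <- model$layers[[which(vapply(model$layers, function(l)
    l$type, character(1)) == "flatten")]]
  expect_equal(prod(flat_layer$in_shape), 16384)
})

test_that("excessive depth on a small input is rejected with a clear error", {
  expect_error(build_cnn(cnn_config(n_conv_blocks = 10)), "too deep")
  # 6 blocks: 64 -> 32 -> 16 -> 8 -> 4 -> 2 -> 1 still feasible
  expect_s3_class(build_cnn(cnn_config(n_conv_blocks = 6)), "cnn_model")
})

test_that("backprop gradients match central finite differences", {
  set.seed(21)
  # tiny 2D network exercising conv2d, maxpool2d, flatten, dense
  net <- structure(list(layers = list(
    drowsEEG:::nn_conv2d(c(6, 6, 2), 3, c(3, 3)),
    drowsEEG:::nn_maxpool2d(c(6, 6, 3), 2),
    drowsEEG:::nn_flatten(c(3, 3, 3)),
    drowsEEG:::nn_dense(27, 5, "relu"),
    drowsEEG:::nn_dense(5, 1, "linear")
  )), class = "cnn_model")
  X <- array(rnorm(6 * 6 * 2 * 4), c(6, 6, 2, 4))
  y <- c(0, 1, 1, 0)
  loss_of <- function(net) {
    drowsEEG:::bce_loss(drowsEEG:::nn_forward(net, X)$logits, y)
  }
  fw <- drowsEEG:::nn_forward(net, X, training = TRUE)
  p <- drowsEEG:::nn_sigmoid(fw$logits[, 1])
  dZ <- matrix((p - y) / length(y), ncol = 1)
  grads <- drowsEEG:::nn_backward(net, fw$caches, dZ)
  eps <- 1e-5
  for (li in c(1, 4, 5)) {
    W <- net$layers[[li]]$W
    for (k in sample(length(W), min(8, length(W)))) {
      np <- net; np$layers[[li]]$W[k] <- W[k] + eps
      nm <- net; nm$layers[[li]]$W[k] <- W[k] - eps
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(grads[[li]]$dW[k], num, tolerance = 1e-4)
    }
    b <- net$layers[[li]]$b
    np <- net; np$layers[[li]]$b[1] <- b[1] + eps
    nm <- net; nm$layers[[li]]$b[1] <- b[1] - eps
    expect_equal(grads[[li]]$db[1],
                 (loss_of(np) - loss_of(nm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("1D conv gradients match finite differences", {
  set.seed(22)
  net <- structure(list(layers = list(
    drowsEEG:::nn_conv1d(c(24, 1), 2, 5),
    drowsEEG:::nn_maxpool1d(c(24, 2), 4),
    drowsEEG:::nn_flatten(c(6, 2)),
    drowsEEG:::nn_dense(12, 1, "linear")
  )), class = "cnn_model")
  X <- array(rnorm(24 * 1 * 3), c(24, 1, 3))
  y <- c(1, 0, 1)
  loss_of <- function(net)
    drowsEEG:::bce_loss(drowsEEG:::nn_forward(net, X)$logits, y)
  fw <- drowsEEG:::nn_forward(net, X, training = TRUE)
  p <- drowsEEG:::nn_sigmoid(fw$logits[, 1])
  grads <- drowsEEG:::nn_backward(net, fw$caches,
                                  matrix((p - y) / length(y), ncol = 1))
  eps <- 1e-5
  W <- net$layers[[1]]$W
  for (k in sample(length(W), 5)) {
    np <- net; np$layers[[1]]$W[k] <- W[k] + eps
    nm <- net; nm$layers[[1]]$W[k] <- W[k] - eps
    expect_equal(grads[[1]]$dW[k],
                 (loss_of(np) - loss_of(nm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("maxpool backward routes gradient only to a single argmax", {
  X <- array(0, c(4, 4, 1, 1))
  X[2, 2, 1, 1] <- 5; X[1, 1, 1, 1] <- 5   # tie inside the first 2x2 window
  layer <- drowsEEG:::nn_maxpool2d(c(4, 4, 1), 2)
  fw <- drowsEEG:::layer_forward(layer, X)
  expect_equal(fw$out[1, 1, 1, 1], 5)
  dOut <- array(1, c(2, 2, 1, 1))
  bk <- drowsEEG:::layer_backward(layer, dOut, fw$cache)
  # each pooled cell passes exactly one unit of gradient
  expect_equal(sum(bk$dX), 4)
  expect_equal(sum(bk$dX[1:2, 1:2, 1, 1]), 1)
})

# small separable image problem shared by the training tests: class 1 images
# are bright in the upper half, class 0 in the lower half, plus noise
make_image_problem <- function(n, h = 12, seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  images <- lapply(seq_len(n), function(i) {
    img <- array(runif(h * h * 3, 0, 0.3), c(h, h, 3))
    rows <- if (labels[i] == 1) 1:(h / 2) else (h / 2 + 1):h
    img[rows, , ] <- img[rows, , ] + 0.6
    img
  })
  list(images = images, labels = labels)
}

test_that("the 2D CNN learns a separable image problem", {
  prob <- make_image_problem(60)
  cfg <- cnn_config(n_conv_blocks = 2, input_shape = c(12, 12, 3))
  tc <- train_config(epochs = 15, batch_size = 16, seed = 5,
                     early_stopping_patience = 15)
  model <- train_cnn(build_cnn(cfg), prob$images[1:40], prob$labels[1:40], tc)
  expect_true(model$trained)
  expect_s3_class(model$history, "data.frame")
  pred <- predict_cnn(model, prob$images[41:60])
  expect_gte(mean(pred$label == prob$labels[41:60]), 0.95)
})

test_that("training is reproducible for a fixed seed", {
  prob <- make_image_problem(24)
  cfg <- cnn_config(input_shape = c(12, 12, 3))
  tc <- train_config(epochs = 3, batch_size = 8, seed = 9,
                     early_stopping_patience = 3)
  m1 <- train_cnn(build_cnn(cfg), prob$images, prob$labels, tc)
  m2 <- train_cnn(build_cnn(cfg), prob$images, prob$labels, tc)
  expect_identical(m1$history, m2$history)
  expect_equal(predict_cnn(m1, prob$images)$score,
               predict_cnn(m2, prob$images)$score, tolerance = 1e-12)
})

test_that("feature extraction returns the 128-d penultimate activations", {
  prob <- make_image_problem(24)
  cfg <- cnn_config(input_shape = c(12, 12, 3))
  tc <- train_config(epochs = 2, batch_size = 8, seed = 2,
                     early_stopping_patience = 2)
  model <- train_cnn(build_cnn(cfg), prob$images, prob$labels, tc)
  f <- extract_features(model, prob$images)
  expect_equal(dim(f), c(24L, 128L))
  expect_true(all(is.finite(f)))
  expect_true(all(f >= 0))                    # post-ReLU
  # deterministic (no dropout at inference)
  expect_identical(f, extract_features(model, prob$images))
  # chunking does not change the result
  expect_equal(f, extract_features(model, prob$images, chunk = 7))
})

test_that("untrained models refuse to predict or extract features", {
  model <- build_cnn(cnn_config(input_shape = c(12, 12, 3)))
  img <- list(array(0.5, c(12, 12, 3)))
  expect_error(predict_cnn(model, img), "not been trained")
  expect_error(extract_features(model, img), "not been trained")
})

test_that("train_cnn validates shapes and labels", {
  prob <- make_image_problem(8)
  model <- build_cnn(cnn_config(input_shape = c(10, 10, 3)))
  expect_error(train_cnn(model, prob$images, prob$labels, train_config()),
               "shape")
  model2 <- build_cnn(cnn_config(input_shape = c(12, 12, 3)))
  expect_error(train_cnn(model2, prob$images, rep(1, 8), train_config()),
               "both classes")
})

test_that("the 1D baseline learns a frequency-discrimination task", {
  set.seed(31)
  fs <- 128; n_per <- 30
  t <- (0:(fs * 2 - 1)) / fs   # 256 samples: 32-wide kernel fits after pooling
  segs <- c(lapply(seq_len(n_per), function(i)
              sin(2 * pi * 5 * t + runif(1, 0, 2 * pi)) + 0.3 * rnorm(length(t))),
            lapply(seq_len(n_per), function(i)
              sin(2 * pi * 14 * t + runif(1, 0, 2 * pi)) + 0.3 * rnorm(length(t))))
  labels <- rep(c(0, 1), each = n_per)
  tr <- c(1:20, 31:50); te <- setdiff(seq_along(labels), tr)
  model <- build_cnn1d(length(t))
  tc <- train_config(epochs = 20, batch_size = 16, seed = 3,
                     early_stopping_patience = 20)
  model <- train_cnn(model, segs[tr], labels[tr], tc)
  acc <- mean(predict_cnn(model, segs[te])$label == labels[te])
  expect_gt(acc, 0.7)
})

test_that("build_cnn1d validates the input length", {
  expect_error(build_cnn1d(32), "shorter than")
  m <- build_cnn1d(512)
  expect_equal(m$kind, "cnn1d")
  expect_identical(m$config$kernels, c(64, 32))
})
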