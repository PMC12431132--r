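#' Filter ladder for a depth-parameterised CNN family
#'
#' Widths double from 16 and are capped at 128; the two-block model keeps
#' the canonical (16, 64) pair.
#'
#' @param n_conv_blocks Number of convolution blocks.
#' @return Integer vector of filter counts.
#' @export
cnn_filter_ladder <- function(n_conv_blocks) {
  if (n_conv_blocks == 2) return(c(16L, 64L))
  as.integer(pmin(16 * 2^(seq_len(n_conv_blocks) - 1), 128))
}

#' CNN configuration
#'
#' @param n_conv_blocks Number of conv-pool-dropout blocks.
#' @param filters_per_block Filter counts (default [cnn_filter_ladder()]).
#' @param kernel Convolution kernel size.
#' @param pool Max-pooling size.
#' @param block_dropout Dropout rate after each block.
#' @param dense_width Width of the penultimate dense (feature) layer.
#' @param head_dropout Dropout rate before the sigmoid head.
#' @param input_shape `c(height, width, channels)` of the input images.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_conv_blocks = 2,
                       filters_per_block = cnn_filter_ladder(n_conv_blocks),
                       kernel = c(3, 3), pool = 2,
                       block_dropout = 0.25, dense_width = 128,
                       head_dropout = 0.5, input_shape = c(64, 64, 3)) {
  if (length(filters_per_block) != n_conv_blocks)
    stop("filters_per_block must have one entry per block")
  if (any(filters_per_block < 1)) stop("all filter counts must be >= 1")
  structure(list(n_conv_blocks = n_conv_blocks,
                 filters_per_block = as.integer(filters_per_block),
                 kernel = kernel, pool = pool,
                 block_dropout = block_dropout, dense_width = dense_width,
                 head_dropout = head_dropout, input_shape = input_shape),
            class = "cnn_config")
}

#' Training configuration
#'
#' Adam optimiser, binary cross-entropy loss, 50 epochs, batch size 32 and
#' early stopping with a patience of 10 epochs by default.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping (set `Inf` to disable).
#' @param validation_fraction Stratified fraction of the training set held
#'   out to monitor early stopping.
#' @param seed RNG seed for weight init, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, learning_rate = 1e-3,
                         early_stopping_patience = 10,
                         validation_fraction = 0.1, seed = 1L) {
  stopifnot(epochs >= 1, early_stopping_patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stopping_patience = early_stopping_patience,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build the depth-parameterised 2D CNN
#'
#' Architecture: `[conv(filters, 3x3, ReLU, same padding) -> maxpool 2x2 ->
#' dropout 0.25] x n_conv_blocks -> flatten -> dense(128, ReLU) ->
#' dropout 0.5 -> dense(1)` trained with a sigmoid/binary cross-entropy
#' head. The 128-unit dense activations are the feature vectors handed to
#' the SVM.
#'
#' @param config A [cnn_config()].
#' @return An object of class `cnn_model` (untrained).
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  shape <- config$input_shape
  layers <- list()
  for (bk in seq_len(config$n_conv_blocks)) {
    layers[[length(layers) + 1L]] <-
      nn_conv2d(shape, config$filters_per_block[bk], config$kernel)
    shape <- layers[[length(layers)]]$out_shape
    pool <- tryCatch(nn_maxpool2d(shape, config$pool), error = function(e)
      stop("network too deep for a ", config$input_shape[1], "x",
           config$input_shape[2], " input: block ", bk, " ", conditionMessage(e),
           call. = FALSE))
    layers[[length(layers) + 1L]] <- pool
    shape <- pool$out_shape
    layers[[length(layers) + 1L]] <- nn_dropout(shape, config$block_dropout)
  }
  layers[[length(layers) + 1L]] <- nn_flatten(shape)
  flat <- prod(shape)
  layers[[length(layers) + 1L]] <- nn_dense(flat, config$dense_width, "relu")
  feature_layer <- length(layers)
  layers[[length(layers) + 1L]] <- nn_dropout(config$dense_width,
                                              config$head_dropout)
  layers[[length(layers) + 1L]] <- nn_dense(config$dense_width, 1, "linear")
  structure(list(layers = layers, config = config,
                 feature_layer = feature_layer, kind = "cnn2d",
                 trained = FALSE),
            class = "cnn_model")
}

#' Build the 1D CNN raw-signal baseline
#'
#' Operates directly on filtered 30-s segments: two convolution blocks with
#' kernel sizes 64 and 32 (ReLU), aggressive max pooling, a dense layer and
#' a dropout rate of 0.5 before the sigmoid head.
#'
#' @param input_length Samples per segment (30 s times the sampling rate).
#' @param filters Filter counts of the two blocks.
#' @param kernels Kernel sizes of the two blocks.
#' @param pool Pooling factor after each block.
#' @param dense_width Dense layer width.
#' @param dropout Dropout rate before the head.
#' @return An object of class `cnn_model`.
#' @export
build_cnn1d <- function(input_length, filters = c(8, 16),
                        kernels = c(64, 32), pool = 8,
                        dense_width = 64, dropout = 0.5) {
  if (input_length < max(kernels))
    stop("input length ", input_length, " shorter than the largest kernel (",
         max(kernels), ")")
  shape <- c(input_length, 1)
  layers <- list()
  for (bk in seq_along(filters)) {
    layers[[length(layers) + 1L]] <- nn_conv1d(shape, filters[bk], kernels[bk])
    shape <- layers[[length(layers)]]$out_shape
    p <- nn_maxpool1d(shape, pool)
    layers[[length(layers) + 1L]] <- p
    shape <- p$out_shape
  }
  layers[[length(layers) + 1L]] <- nn_flatten(shape)
  layers[[length(layers) + 1L]] <- nn_dense(prod(shape), dense_width, "relu")
  feature_layer <- length(layers)
  layers[[length(layers) + 1L]] <- nn_dropout(dense_width, dropout)
  layers[[length(layers) + 1L]] <- nn_dense(dense_width, 1, "linear")
  structure(list(layers = layers,
                 config = list(kernels = kernels, filters = filters,
                               pool = pool, dense_width = dense_width,
                               dropout = dropout,
                               input_length = input_length),
                 feature_layer = feature_layer, kind = "cnn1d",
                 trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model %s> %d layers, %s parameters, %strained\n",
              x$kind, length(x$layers),
              format(nn_param_count(x), big.mark = ","),
              if (x$trained) "" else "un"))
  invisible(x)
}

#' Total trainable parameters of a model
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) nn_param_count(model)

# stack a list of images/segments into the batch tensor the engine expects
as_input_tensor <- function(inputs, kind) {
  if (is.array(inputs) && !is.list(inputs)) return(inputs)
  if (kind == "cnn2d") {
    d <- dim(inputs[[1]])
    X <- array(0, c(d, length(inputs)))
    for (i in seq_along(inputs)) X[, , , i] <- inputs[[i]]
  } else {
    n <- length(inputs[[1]])
    X <- array(0, c(n, 1, length(inputs)))
    for (i in seq_along(inputs)) X[, 1, i] <- as.numeric(inputs[[i]])
  }
  X
}

slice_batch <- function(X, idx) {
  nd <- length(dim(X))
  if (nd == 4) X[, , , idx, drop = FALSE] else X[, , idx, drop = FALSE]
}

#' Train a CNN with Adam and early stopping
#'
#' Minimises binary cross-entropy with minibatch Adam. A stratified
#' validation split of the training data monitors early stopping (patience
#' in epochs); the weights of the best validation epoch are restored.
#' Reproducible for a fixed seed.
#'
#' @param model A `cnn_model` from [build_cnn()] or [build_cnn1d()].
#' @param inputs List of input arrays (images for 2D, numeric segments for
#'   1D) or a pre-stacked batch tensor.
#' @param labels Binary labels (0 alert / 1 drowsy).
#' @param tc A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a `history` data frame (epoch, loss,
#'   accuracy, val_loss, val_accuracy) attached.
#' @export
train_cnn <- function(model, inputs, labels, tc = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes")
  X <- as_input_tensor(inputs, model$kind)
  n <- length(labels)
  exp_in <- if (model$kind == "cnn2d") model$config$input_shape
            else c(model$config$input_length, 1)
  got <- utils::head(dim(X), -1)
  if (!all(got == exp_in))
    stop("input shape (", paste(got, collapse = "x"),
         ") does not match the model input (",
         paste(exp_in, collapse = "x"), ")")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tc$seed)
  # fresh seeded weights so training is reproducible end to end
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (!is.null(l$W)) {
      fan_in <- nrow(l$W)
      model$layers[[i]]$W <- matrix(he_init(fan_in, length(l$W)),
                                    nrow(l$W), ncol(l$W))
      model$layers[[i]]$b <- numeric(length(l$b))
    }
  }

  # stratified validation split
  val_idx <- integer(0)
  if (tc$validation_fraction > 0 && n >= 10) {
    for (cl in unique(labels)) {
      ids <- which(labels == cl)
      k <- max(1, round(length(ids) * tc$validation_fraction))
      val_idx <- c(val_idx, sample(ids, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xval <- if (length(val_idx)) slice_batch(X, val_idx) else NULL
  yval <- labels[val_idx]

  state <- adam_init(model)
  step <- 0L
  best_val <- Inf
  best_layers <- NULL
  wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), val_loss = numeric(0),
                     val_accuracy = numeric(0))
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, length(ord), by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1, length(ord))]
      Xb <- slice_batch(X, idx)
      yb <- labels[idx]
      fw <- nn_forward(model, Xb, training = TRUE)
      z <- fw$logits[, 1]
      p <- nn_sigmoid(z)
      ep_loss <- ep_loss + bce_loss(fw$logits, yb) * length(idx)
      ep_correct <- ep_correct + sum(as.integer(p > 0.5) == yb)
      dZ <- matrix((p - yb) / length(idx), ncol = 1)
      grads <- nn_backward(model, fw$caches, dZ)
      step <- step + 1L
      upd <- adam_step(model, grads, state, tc$learning_rate, step)
      model <- upd$net
      state <- upd$state
    }
    tr_loss <- ep_loss / length(tr_idx)
    tr_acc <- ep_correct / length(tr_idx)
    if (!is.null(Xval)) {
      vz <- nn_forward(model, Xval)$logits
      v_loss <- bce_loss(vz, yval)
      v_acc <- mean(as.integer(nn_sigmoid(vz[, 1]) > 0.5) == yval)
    } else {
      v_loss <- tr_loss; v_acc <- tr_acc
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = tr_loss,
                                   accuracy = tr_acc, val_loss = v_loss,
                                   val_accuracy = v_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                      epoch, tr_loss, tr_acc, v_loss, v_acc))
    if (v_loss < best_val - 1e-6) {
      best_val <- v_loss
      best_layers <- model$layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$early_stopping_patience) break
    }
  }
  if (!is.null(best_layers)) model$layers <- best_layers
  model$trained <- TRUE
  model$history <- hist
  model$train_config <- tc
  model
}

#' Classify inputs with a trained CNN
#'
#' @param model Trained `cnn_model`.
#' @param inputs Input list or batch tensor.
#' @param chunk Evaluate at most this many inputs per forward pass.
#' @return data.frame with `score` (sigmoid probability of drowsy) and
#'   `label`.
#' @export
predict_cnn <- function(model, inputs, chunk = 256) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  X <- as_input_tensor(inputs, model$kind)
  n <- utils::tail(dim(X), 1)
  scores <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    scores[idx] <- nn_sigmoid(nn_forward(model, slice_batch(X, idx))$logits[, 1])
  }
  data.frame(score = scores, label = as.integer(scores > 0.5))
}

#' Extract penultimate-layer feature vectors
#'
#' Returns the activations of the 128-unit dense layer (post-ReLU, without
#' the inference-time dropout), one row per input. Deterministic given the
#' trained weights.
#'
#' @param model Trained `cnn_model`.
#' @param inputs Input list or batch tensor.
#' @param chunk Inputs per forward pass.
#' @return Numeric matrix (n inputs x feature width).
#' @export
extract_features <- function(model, inputs, chunk = 256) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  X <- as_input_tensor(inputs, model$kind)
  n <- utils::tail(dim(X), 1)
  width <- model$layers[[model$feature_layer]]$out_shape
  out <- matrix(0, n, width)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    fw <- nn_forward(model, slice_batch(X, idx), keep = model$feature_layer)
    out[idx, ] <- fw$kept
  }
  if (any(!is.finite(out))) stop("non-finite feature values")
  out
}
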