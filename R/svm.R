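#' SVM head configuration
#'
#' Soft-margin SVM on CNN feature vectors. The RBF kernel follows the
#' `exp(-gamma * ||x - x'||^2)` convention, so the published optimum
#' (C = 1, gamma = 0.4) maps directly onto `C` and `gamma`.
#'
#' @param kernel One of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param C Penalty parameter (> 0).
#' @param gamma Kernel factor (> 0; ignored by the linear kernel).
#' @param degree Polynomial degree (polynomial kernel only).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = "rbf", C = 1, gamma = 0.4, degree = 3) {
  kernel <- match.arg(kernel, c("linear", "polynomial", "rbf", "sigmoid"))
  if (C <= 0) stop("C must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (kernel == "polynomial" && degree < 2) stop("degree must be >= 2")
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 degree = as.integer(degree)),
            class = "svm_config")
}

kernel_to_libsvm <- function(kernel) {
  c(linear = "linear", polynomial = "polynomial", rbf = "radial",
    sigmoid = "sigmoid")[[kernel]]
}

#' Fit an SVM head on feature vectors
#'
#' Standardises each feature dimension to zero mean / unit standard
#' deviation (statistics estimated on the training data only) and solves the
#' soft-margin dual with the configured kernel. The positive class is drowsy
#' (label 1).
#'
#' @param features Numeric matrix (n x d).
#' @param labels Binary labels in \{0, 1\}.
#' @param config An [svm_config()].
#' @param standardize Standardise features before fitting (default TRUE).
#' @return An object of class `trained_svm` holding the fitted model, the
#'   configuration and the scaling parameters.
#' @export
fit_svm <- function(features, labels, config = svm_config(),
                    standardize = TRUE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (length(unique(labels)) < 2)
    stop("need at least one sample of each class")
  if (standardize) {
    mu <- colMeans(features)
    sdev <- apply(features, 2, sd)
    sdev[sdev == 0 | !is.finite(sdev)] <- 1
  } else {
    mu <- rep(0, ncol(features)); sdev <- rep(1, ncol(features))
  }
  xs <- scale(features, center = mu, scale = sdev)
  fit <- e1071::svm(x = xs, y = factor(labels, levels = c(0, 1)),
                    scale = FALSE,
                    kernel = kernel_to_libsvm(config$kernel),
                    cost = config$C, gamma = config$gamma,
                    degree = config$degree, coef0 = 0)
  structure(list(fit = fit, config = config, center = mu, scale = sdev,
                 n_support = sum(fit$nSV), d = ncol(features)),
            class = "trained_svm")
}

#' @export
print.trained_svm <- function(x, ...) {
  cat(sprintf("<trained_svm> kernel=%s C=%g gamma=%g, %d support vectors\n",
              x$config$kernel, x$config$C, x$config$gamma, x$n_support))
  invisible(x)
}

#' Predict vigilance labels and scores
#'
#' The continuous score is the signed distance to the separating
#' hyperplane, oriented so that positive means drowsy; labels follow the
#' sign with boundary ties assigned to the alert class (0).
#'
#' @param object A `trained_svm`.
#' @param features Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return data.frame with columns `score` and `label`.
#' @export
predict.trained_svm <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$d)
    stop("feature dimension (", ncol(features),
         ") does not match the fitted model (", object$d, ")")
  xs <- scale(features, center = object$center, scale = object$scale)
  pr <- predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision value toward the first class of the column
  # name "A/B": positive means class A
  pos_class <- strsplit(colnames(dv)[1], "/")[[1]][1]
  score <- if (pos_class == "1") dv[, 1] else -dv[, 1]
  data.frame(score = as.numeric(score),
             label = as.integer(score > 0))
}

stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- sample(which(labels == cl))
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

#' Grid search over SVM hyperparameters
#'
#' Stratified k-fold cross-validation on the training partition only. The
#' best cell maximises mean CV accuracy; ties break toward smaller C, then
#' smaller gamma.
#'
#' @param features Training feature matrix.
#' @param labels Training labels.
#' @param kernel Kernel to tune.
#' @param C_grid,gamma_grid,degree_grid Candidate values. `gamma_grid` is
#'   ignored for the linear kernel, `degree_grid` for all but the
#'   polynomial kernel.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return List with `best` (an [svm_config()]) and `cv_table`
#'   (one row per grid cell, per-fold accuracies and their mean).
#' @export
grid_search_svm <- function(features, labels, kernel = "rbf",
                            C_grid = c(0.01, 0.1, 1, 10, 100),
                            gamma_grid = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                            degree_grid = c(2, 3, 4),
                            k = 5, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(C_grid) < 1) stop("empty grid")
  if (k > min(table(labels)))
    stop("fold count (", k, ") exceeds the minority-class size")
  gammas <- if (kernel == "linear") 0.4 else gamma_grid
  degrees <- if (kernel == "polynomial") degree_grid else 3
  grid <- expand.grid(C = C_grid, gamma = gammas, degree = degrees,
                      KEEP.OUT.ATTRS = FALSE)
  fold <- stratified_folds(labels, k, seed)
  acc <- matrix(NA_real_, nrow(grid), k)
  for (g in seq_len(nrow(grid))) {
    cfg <- svm_config(kernel, C = grid$C[g], gamma = grid$gamma[g],
                      degree = grid$degree[g])
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- fit_svm(features[tr, , drop = FALSE], labels[tr], cfg)
      p <- predict(m, features[!tr, , drop = FALSE])
      acc[g, f] <- mean(p$label == labels[!tr])
    }
  }
  cv <- cbind(grid, acc, mean_accuracy = rowMeans(acc))
  names(cv)[3 + seq_len(k)] <- paste0("fold", seq_len(k))
  ord <- order(-cv$mean_accuracy, cv$C, cv$gamma, cv$degree)
  best_row <- cv[ord[1], ]
  list(best = svm_config(kernel, C = best_row$C, gamma = best_row$gamma,
                         degree = best_row$degree),
       cv_table = cv)
}
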