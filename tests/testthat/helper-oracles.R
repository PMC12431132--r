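# Independent oracles used across the test files. These deliberately avoid
# the package's own implementations.

# ---- SVM dual oracle: simplified SMO (Platt) on the soft-margin dual -------
# Solves max sum(alpha) - 1/2 alpha' Q alpha, 0 <= alpha <= C,
# sum(alpha * y) = 0, with Q_ij = y_i y_j K(x_i, x_j). Intended for n <= 20.
oracle_kernel <- function(X1, X2, kernel, gamma = 0.4, degree = 3) {
  if (kernel == "linear") return(X1 %*% t(X2))
  if (kernel == "rbf") {
    d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
    return(exp(-gamma * pmax(d2, 0)))
  }
  if (kernel == "polynomial") return((gamma * X1 %*% t(X2))^degree)
  stop("unsupported kernel in oracle")
}

oracle_svm_smo <- function(X, y01, C, kernel = "linear", gamma = 0.4,
                           tol = 1e-8, max_passes = 2000) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- length(y)
  K <- oracle_kernel(X, X, kernel, gamma)
  alpha <- numeric(n)
  b <- 0
  f <- function(i) sum(alpha * y * K[, i]) + b
  passes <- 0
  while (passes < max_passes) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- f(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        for (j in setdiff(seq_len(n), i)) {
          Ej <- f(j) - y[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (y[i] != y[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - y[j] * (Ei - Ej) / eta
          aj <- min(max(aj, L), H)
          if (abs(aj - aj_old) < 1e-12) next
          ai <- ai_old + y[i] * y[j] * (aj_old - aj)
          alpha[i] <- ai; alpha[j] <- aj
          b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
            y[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
            y[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1
               else if (aj > 0 && aj < C) b2
               else (b1 + b2) / 2
          changed <- changed + 1L
          break
        }
      }
    }
    passes <- if (changed == 0L) passes + 1 else 0
    if (changed == 0L && passes >= 3) break
  }
  list(alpha = alpha, b = b, y = y,
       decision = function(Xnew) {
         Knew <- oracle_kernel(as.matrix(Xnew), X, kernel, gamma)
         as.numeric(Knew %*% (alpha * y) + b)
       })
}

# ---- confusion-metric formula oracle ---------------------------------------
oracle_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  p <- div(tp, tp + fp); r <- div(tp, tp + fn)
  list(accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
       sensitivity = r,
       specificity = div(tn, tn + fp),
       precision = p,
       f1 = if (!is.na(p) && !is.na(r) && p + r > 0)
         2 * p * r / (p + r) else NA_real_)
}

# ---- ROC AUC oracle: Mann-Whitney pairwise ordering ------------------------
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# ---- band power oracle: raw periodogram ------------------------------------
oracle_band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
}

# ---- shared small fixtures --------------------------------------------------
tiny_sim_config <- function(...) {
  args <- list(sampling_rate = 128, session_duration = 60, n_subjects = 3,
               n_sessions_per_subject = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# scalogram_dataset with constant tiny images; labels as given
tiny_dataset <- function(labels, h = 4, w = 4) {
  images <- lapply(seq_along(labels), function(i)
    array(i / length(labels), dim = c(h, w, 3)))
  meta <- data.frame(subject = 1, session = 1, channel = "C3",
                     start = seq_along(labels), label = labels,
                     augmented = FALSE)
  structure(list(images = images, meta = meta,
                 params = list(scales = 1, colormap = "viridis",
                               native_size = c(w, h),
                               storage_size = c(w, h),
                               input_size = c(w, h))),
            class = "scalogram_dataset")
}
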