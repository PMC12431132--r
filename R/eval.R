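# Evaluation: class balancing, train/test splits, confusion-matrix metrics,
# PR/ROC curves and the depth-ablation / kernel-comparison drivers.
# Positive class = drowsy (label 1) throughout.

#' Confusion matrix for binary vigilance classification
#'
#' @param truth,predicted Equal-length binary label vectors (0 alert,
#'   1 drowsy).
#' @return Object of class `confusion_2x2` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors have different lengths")
  if (!all(c(truth, predicted) %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  structure(list(
    tp = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 0 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fn = sum(truth == 1 & predicted == 0)
  ), class = "confusion_2x2")
}

#' Build a confusion matrix from counts
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_2x2`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("alert", "drowsy"),
                              actual = c("alert", "drowsy")))
  print(m)
  invisible(x)
}

# round-half-up at display precision (printed tables use 2 decimals)
round_half_up <- function(x, digits = 2) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall on the drowsy class), specificity,
#' precision and F1 as percentages, kept at full precision; use
#' `format()` for the conventional 2-decimal display.
#' A metric with a zero denominator is reported as `NA` (not applicable).
#'
#' @param cm A `confusion_2x2`.
#' @param scores,truth Optional continuous scores and true labels; when
#'   given, PR and ROC AUCs are included.
#' @return Object of class `metrics_report`.
#' @export
compute_metrics <- function(cm, scores = NULL, truth = NULL) {
  stopifnot(inherits(cm, "confusion_2x2"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  recall <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  rep <- list(
    accuracy = 100 * (cm$tp + cm$tn) / n,
    sensitivity = recall,
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    precision = precision,
    f1 = f1,
    confusion = cm, n = n
  )
  if (!is.null(scores) && !is.null(truth)) {
    cv <- binary_curves(scores, truth)
    rep$roc_auc <- cv$roc_auc
    rep$pr_auc <- cv$pr_auc
  }
  structure(rep, class = "metrics_report")
}

#' @export
format.metrics_report <- function(x, digits = 2, ...) {
  fmt <- function(v) if (is.na(v)) "n/a"
    else formatC(round_half_up(v, digits), format = "f", digits = digits)
  out <- c(accuracy = fmt(x$accuracy), sensitivity = fmt(x$sensitivity),
           specificity = fmt(x$specificity), precision = fmt(x$precision),
           f1 = fmt(x$f1))
  if (!is.null(x$roc_auc))
    out <- c(out, roc_auc = formatC(x$roc_auc, format = "f", digits = 4),
             pr_auc = formatC(x$pr_auc, format = "f", digits = 4))
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  f <- format(x)
  cat(sprintf("accuracy %s%%  sensitivity %s%%  specificity %s%%  precision %s%%  F1 %s%%\n",
              f["accuracy"], f["sensitivity"], f["specificity"],
              f["precision"], f["f1"]))
  if (!is.null(x$roc_auc))
    cat(sprintf("ROC AUC %s  PR AUC %s\n", f["roc_auc"], f["pr_auc"]))
  invisible(x)
}

#' Precision-recall and ROC curves with AUCs
#'
#' Sweeps the decision threshold over the unique scores. ROC AUC is the
#' trapezoidal area; PR AUC uses step-wise interpolation (average
#' precision).
#'
#' @param scores Continuous classifier scores (higher = more drowsy).
#' @param truth Binary true labels.
#' @return List with `roc` (data.frame fpr/tpr), `pr` (recall/precision),
#'   `roc_auc`, `pr_auc`.
#' @export
binary_curves <- function(scores, truth) {
  truth <- as.integer(truth)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(truth)) < 2)
    stop("both classes must be present to compute curves")
  np <- sum(truth == 1); nn <- sum(truth == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # merge tied scores into single threshold steps
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / np
  prec <- tp / (tp + fp)
  # average precision: sum of precision * recall increments
  pr_auc <- sum(diff(c(0, recall)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = recall, precision = prec),
       roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Balance classes by augmenting the minority with new scalograms
#'
#' Raises the minority class (normally drowsy) to the majority-class size.
#' When the source segments and recordings are available, new minority
#' scalograms are generated from 50%-overlapping re-windowing of the source
#' signal; any remaining deficit (and the no-source fallback) is covered by
#' small circular time-axis shifts of existing minority images. Augmented
#' samples are flagged in the `augmented` metadata column. Original samples
#' are never removed.
#'
#' @param dataset A `scalogram_dataset` from [segments_to_scalograms()].
#' @param recordings Optional named list of filtered recordings (names
#'   `"subject.session"`) enabling signal-domain re-windowing.
#' @param window Window length in seconds (matching the original
#'   segmentation).
#' @param channels Channels used at segmentation time.
#' @return The balanced `scalogram_dataset`.
#' @export
balance_by_augmentation <- function(dataset, recordings = NULL,
                                    window = 30, channels = c("C3", "C4")) {
  stopifnot(inherits(dataset, "scalogram_dataset"))
  lab <- dataset$meta$label
  n0 <- sum(lab == 0); n1 <- sum(lab == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present")
  if (n0 == n1) return(dataset)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)

  new_images <- list()
  new_meta <- dataset$meta[0, ]

  if (!is.null(recordings)) {
    # 50%-overlap re-windowing of minority-class source recordings
    min_rows <- dataset$meta[dataset$meta$label == minority &
                               !dataset$meta$augmented, ]
    keys <- unique(min_rows[, c("subject", "session")])
    for (r in seq_len(nrow(keys))) {
      if (length(new_images) >= need) break
      rec <- recordings[[paste(keys$subject[r], keys$session[r], sep = ".")]]
      if (is.null(rec)) next
      w <- round(window * rec$sampling_rate)
      n <- length(rec$samples[[1]])
      offsets <- seq(w %/% 2, n - w, by = w)   # half-window offsets
      for (ch in intersect(channels, rec$channel_names)) {
        for (o in offsets) {
          if (length(new_images) >= need) break
          seg <- structure(list(
            samples = rec$samples[[ch]][(o + 1):(o + w)],
            sampling_rate = rec$sampling_rate,
            subject_id = rec$subject_id, session_id = rec$session_id,
            channel = ch, start_index = o, duration = window,
            label = minority
          ), class = "eeg_segment")
          aug <- segments_to_scalograms(
            list(seg), scales = dataset$params$scales,
            colormap = dataset$params$colormap,
            native_size = dataset$params$native_size,
            storage_size = dataset$params$storage_size,
            input_size = dataset$params$input_size)
          new_images <- c(new_images, aug$images)
          row <- aug$meta; row$augmented <- TRUE
          new_meta <- rbind(new_meta, row)
        }
      }
    }
  }

  # image-domain fallback: circular shifts along the time axis
  if (length(new_images) < need) {
    src_idx <- which(lab == minority)
    width <- dim(dataset$images[[src_idx[1]]])[2]
    extra <- need - length(new_images)
    shifted <- vector("list", extra)
    from_all <- integer(extra)
    for (i in seq_len(extra)) {
      from <- src_idx[((i - 1) %% length(src_idx)) + 1]
      shift <- (((i - 1) %/% length(src_idx)) %% (width - 1)) + 1L
      img <- dataset$images[[from]]
      shifted[[i]] <- img[, c((shift + 1):width, 1:shift), , drop = FALSE]
      from_all[i] <- from
    }
    new_images <- c(new_images, shifted)
    rows <- dataset$meta[from_all, , drop = FALSE]
    rows$augmented <- TRUE
    new_meta <- rbind(new_meta, rows)
  }

  dataset$images <- c(dataset$images, new_images)
  dataset$meta <- rbind(dataset$meta, new_meta)
  rownames(dataset$meta) <- NULL
  dataset
}

#' Train/test split specification
#'
#' @param mode `"pooled_random"` (stratified sample-level split, the
#'   published protocol) or `"leave_subjects_out"` (whole subjects held
#'   out; no subject appears in both partitions).
#' @param train_fraction Fraction of samples assigned to training.
#' @param stratified Stratify the pooled split by class.
#' @param seed RNG seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(mode = c("pooled_random", "leave_subjects_out"),
                       train_fraction = 0.7, stratified = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(mode = mode, train_fraction = train_fraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

#' Assign samples to train/test partitions
#'
#' @param meta data.frame with at least `label` and (for subject-wise
#'   splitting) `subject` columns; one row per sample.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive) and the spec.
#' @export
make_split <- function(meta, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), nrow(meta) >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- nrow(meta)
  if (spec$mode == "pooled_random") {
    if (spec$stratified) {
      train <- integer(0)
      for (cl in unique(meta$label)) {
        ids <- which(meta$label == cl)
        k <- round(length(ids) * spec$train_fraction)
        k <- min(max(k, 1), length(ids) - 1)
        train <- c(train, sample(ids, k))
      }
    } else {
      train <- sample(n, round(n * spec$train_fraction))
    }
  } else {
    subjects <- unique(meta$subject)
    if (length(subjects) < 2)
      stop("leave_subjects_out needs at least 2 subjects")
    perm <- sample(subjects)
    sizes <- vapply(perm, function(s) sum(meta$subject == s), numeric(1))
    target_test <- (1 - spec$train_fraction) * n
    csum <- cumsum(sizes)
    k <- which.min(abs(csum - target_test))
    k <- min(max(k, 1), length(subjects) - 1)
    test_subjects <- perm[seq_len(k)]
    train <- which(!meta$subject %in% test_subjects)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train), spec = spec)
}

metrics_row <- function(report) {
  data.frame(accuracy = report$accuracy, sensitivity = report$sensitivity,
             f1 = report$f1, precision = report$precision,
             specificity = report$specificity)
}

#' Depth ablation of the CNN family
#'
#' Trains one model per requested depth with an identical seed and split and
#' evaluates each on the test partition with its own sigmoid head. Depths
#' that are infeasible for the input size are reported per row rather than
#' failing the run.
#'
#' @param images List of network-input images.
#' @param labels Binary labels.
#' @param train_idx,test_idx Partition indices from [make_split()].
#' @param depths Depths to evaluate.
#' @param tc A [train_config()].
#' @param input_shape Image shape.
#' @return data.frame: one row per depth with the five metrics (percent)
#'   and a `feasible` flag.
#' @export
run_depth_ablation <- function(images, labels, train_idx, test_idx,
                               depths = c(1, 2, 3, 5, 10),
                               tc = train_config(),
                               input_shape = c(64, 64, 3)) {
  rows <- lapply(depths, function(d) {
    model <- tryCatch(
      build_cnn(cnn_config(n_conv_blocks = d, input_shape = input_shape)),
      error = function(e) e)
    if (inherits(model, "error")) {
      return(cbind(data.frame(depth = d, feasible = FALSE,
                              note = conditionMessage(model)),
                   metrics_row(structure(list(accuracy = NA_real_,
                                              sensitivity = NA_real_,
                                              f1 = NA_real_,
                                              precision = NA_real_,
                                              specificity = NA_real_),
                                         class = "metrics_report"))))
    }
    model <- train_cnn(model, images[train_idx], labels[train_idx], tc)
    pred <- predict_cnn(model, images[test_idx])
    rep <- compute_metrics(confusion(labels[test_idx], pred$label))
    cbind(data.frame(depth = d, feasible = TRUE, note = ""),
          metrics_row(rep))
  })
  do.call(rbind, rows)
}

#' Compare SVM kernels on extracted features
#'
#' Grid-searches each kernel on the training partition, fits the best
#' configuration and evaluates on the test partition. Also reports each
#' kernel's accuracy gap to the best kernel.
#'
#' @param features Feature matrix (n x d).
#' @param labels Binary labels.
#' @param train_idx,test_idx Partition indices.
#' @param kernels Kernels to compare.
#' @param k Cross-validation folds for the grid search.
#' @param seed Seed for fold assignment.
#' @param ... Passed to [grid_search_svm()] (grids).
#' @return data.frame: one row per kernel with the five metrics (percent),
#'   the selected C/gamma/degree and `gap_to_best` (percentage points).
#' @export
run_kernel_comparison <- function(features, labels, train_idx, test_idx,
                                  kernels = c("rbf", "linear",
                                              "polynomial", "sigmoid"),
                                  k = 5, seed = 1L, ...) {
  rows <- lapply(kernels, function(kn) {
    gs <- grid_search_svm(features[train_idx, , drop = FALSE],
                          labels[train_idx], kernel = kn, k = k,
                          seed = seed, ...)
    m <- fit_svm(features[train_idx, , drop = FALSE], labels[train_idx],
                 gs$best)
    p <- predict(m, features[test_idx, , drop = FALSE])
    rep <- compute_metrics(confusion(labels[test_idx], p$label))
    cbind(data.frame(kernel = kn, C = gs$best$C, gamma = gs$best$gamma,
                     degree = gs$best$degree),
          metrics_row(rep))
  })
  tab <- do.call(rbind, rows)
  tab$gap_to_best <- max(tab$accuracy) - tab$accuracy
  tab
}
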