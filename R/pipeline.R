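#' Run the full synthetic drowsiness-detection pipeline
#'
#' End-to-end driver: simulate a cohort, band-pass filter, segment into
#' windows, render Morlet scalograms, balance classes by augmentation,
#' split, train the CNN, extract penultimate features, fit the SVM head and
#' evaluate on the held-out partition. Every stage derives its seed from the
#' global `seed` (seed plus stage index), so a run is reproducible from its
#' arguments.
#'
#' @param config A [sim_config()] describing the cohort.
#' @param seed Global seed fanned out to the stages.
#' @param low,high Band-pass edges in Hz.
#' @param window Segment length in seconds.
#' @param channels Channels to segment.
#' @param scales Wavelet scales (default [default_scales()]).
#' @param input_size Network input image size.
#' @param cnn A [cnn_config()]; its `input_shape` is aligned with
#'   `input_size`.
#' @param tc A [train_config()] (its seed is overridden by the fan-out).
#' @param svm Either an [svm_config()] used as-is, or `"grid"` to
#'   grid-search the kernel's hyperparameters on the training partition.
#' @param svm_kernel Kernel for the SVM head.
#' @param split A [split_spec()] (its seed is overridden by the fan-out).
#' @param balance Balance classes by augmentation before splitting (the
#'   published order). Note this can leak augmented near-duplicates across
#'   partitions; set `augment_after_split = TRUE` for the conservative
#'   order.
#' @param augment_after_split Restrict augmentation to the training
#'   partition.
#' @param shuffle_labels Permute labels after balancing (chance-level
#'   control).
#' @param verbose Print stage progress.
#' @return List with the trained `cnn`, `svm`, `metrics` (a
#'   `metrics_report` with AUCs), `confusion`, `curves`, `split`, dataset
#'   counts, the extracted `features_train`/`features_test` with their
#'   labels and scores, and the per-stage seeds.
#' @export
run_drowsiness_pipeline <- function(config = sim_config(),
                                    seed = 1L,
                                    low = 0.1, high = 30,
                                    window = 30,
                                    channels = c("C3", "C4"),
                                    scales = NULL,
                                    input_size = c(64, 64),
                                    cnn = cnn_config(),
                                    tc = train_config(),
                                    svm = svm_config(),
                                    svm_kernel = "rbf",
                                    split = split_spec(),
                                    balance = TRUE,
                                    augment_after_split = FALSE,
                                    shuffle_labels = FALSE,
                                    verbose = FALSE) {
  seeds <- stats::setNames(vapply(1:6, function(i) derive_seed(seed, 100L + i),
                                  integer(1)),
                           c("simulate", "shuffle", "split", "cnn", "svm",
                             "augment"))
  say <- function(...) if (verbose) message(sprintf(...))

  config$seed <- seeds[["simulate"]]
  say("simulating %d subjects x %d sessions", config$n_subjects,
      config$n_sessions_per_subject)
  cohort <- simulate_cohort(config)

  fir <- design_bandpass(low, high, config$sampling_rate)
  say("filtering and segmenting")
  recordings <- list()
  segments <- list()
  for (rec in cohort) {
    f <- apply_filter(rec, fir)
    recordings[[paste(f$subject_id, f$session_id, sep = ".")]] <- f
    segments <- c(segments, segment_recording(f, window, channels))
  }

  say("rendering %d scalograms", length(segments))
  dataset <- segments_to_scalograms(segments, scales = scales,
                                    input_size = input_size)

  if (balance && !augment_after_split) {
    dataset <- balance_by_augmentation(dataset, recordings,
                                       window = window, channels = channels)
    say("balanced to %d images", length(dataset$images))
  }

  if (shuffle_labels) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seeds[["shuffle"]])
    dataset$meta$label <- sample(dataset$meta$label)
  }

  split$seed <- seeds[["split"]]
  parts <- make_split(dataset$meta, split)

  if (balance && augment_after_split) {
    warning("augmenting after the split: partition sizes will differ from ",
            "the balanced-before-split protocol")
    train_ds <- dataset
    train_ds$images <- dataset$images[parts$train]
    train_ds$meta <- dataset$meta[parts$train, ]
    train_ds <- balance_by_augmentation(train_ds, recordings,
                                        window = window, channels = channels)
    images_train <- train_ds$images
    labels_train <- train_ds$meta$label
  } else {
    images_train <- dataset$images[parts$train]
    labels_train <- dataset$meta$label[parts$train]
  }
  images_test <- dataset$images[parts$test]
  labels_test <- dataset$meta$label[parts$test]

  cnn$input_shape <- c(input_size[2], input_size[1], 3)
  tc$seed <- seeds[["cnn"]]
  say("training CNN (%d train images)", length(images_train))
  model <- build_cnn(cnn)
  model <- train_cnn(model, images_train, labels_train, tc)

  say("extracting features and fitting SVM")
  feat_train <- extract_features(model, images_train)
  feat_test <- extract_features(model, images_test)
  if (identical(svm, "grid")) {
    gs <- grid_search_svm(feat_train, labels_train, kernel = svm_kernel,
                          seed = seeds[["svm"]])
    svm <- gs$best
  }
  head_svm <- fit_svm(feat_train, labels_train, svm)
  pred <- predict(head_svm, feat_test)

  cm <- confusion(labels_test, pred$label)
  metrics <- compute_metrics(cm, scores = pred$score, truth = labels_test)
  curves <- binary_curves(pred$score, labels_test)
  say("test accuracy %.2f%%", metrics$accuracy)

  list(metrics = metrics, confusion = cm, curves = curves,
       cnn = model, svm = head_svm, split = parts,
       n_images = length(dataset$images),
       n_train = length(images_train), n_test = length(images_test),
       features_train = feat_train, features_test = feat_test,
       labels_train = labels_train, labels_test = labels_test,
       scores_test = pred$score, seeds = seeds)
}
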