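# Metrics, curves, balancing and splitting.

test_that("confusion() agrees with direct counting", {
  set.seed(51)
  truth <- rbinom(200, 1, 0.4)
  pred <- rbinom(200, 1, 0.5)
  cm <- confusion(truth, pred)
  expect_equal(cm$tp, sum(truth == 1 & pred == 1))
  expect_equal(cm$fp, sum(truth == 0 & pred == 1))
  expect_equal(cm$tn, sum(truth == 0 & pred == 0))
  expect_equal(cm$fn, sum(truth == 1 & pred == 0))
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "length")
  expect_error(confusion(c(0, 2), c(0, 1)), "binary")
})

test_that("metric identities hold on 100 random confusion matrices", {
  set.seed(52)
  for (i in 1:100) {
    cts <- rpois(4, lambda = sample(c(2, 20, 200), 1))
    if (sum(cts) == 0) cts[1] <- 1
    m <- compute_metrics(confusion_counts(cts[1], cts[2], cts[3], cts[4]))
    o <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    for (k in names(o)) expect_equal(m[[k]], o[[k]], info = k)
    # structural identities
    if (!is.na(m$sensitivity) && !is.na(m$specificity)) {
      n1 <- cts[1] + cts[4]; n0 <- cts[2] + cts[3]
      expect_equal(m$accuracy,
                   (m$sensitivity * n1 + m$specificity * n0) / (n1 + n0))
    }
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 100 * 2 * cts[1] / (2 * cts[1] + cts[2] + cts[4]))
    }
  }
})

test_that("zero-denominator metrics come back as NA, not NaN or error", {
  m <- compute_metrics(confusion_counts(0, 0, 10, 0))  # no positives at all
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 100)
  expect_identical(unname(format(m)["sensitivity"]), "n/a")
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("display rounding is half-up at 2 decimals", {
  expect_equal(drowsEEG:::round_half_up(96.665), 96.67)
  expect_equal(drowsEEG:::round_half_up(96.664), 96.66)
  # 0.125 is exactly representable, so the half-tie is genuine
  expect_equal(drowsEEG:::round_half_up(0.125), 0.13)
  expect_equal(drowsEEG:::round_half_up(-0.125), -0.13)
  m <- compute_metrics(confusion_counts(1, 2, 1, 0))
  expect_identical(unname(format(m)["precision"]), "33.33")
})

test_that("ROC AUC equals the Mann-Whitney pairwise-ordering oracle", {
  set.seed(53)
  for (i in 1:20) {
    n <- 40
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
    scores <- rnorm(n) + truth * runif(1, 0, 2)
    if (i %% 3 == 0) scores <- round(scores)   # force ties
    cv <- binary_curves(scores, truth)
    expect_equal(cv$roc_auc, oracle_auc(scores, truth), tolerance = 1e-12)
  }
})

test_that("curves agree with pROC on a fixed example", {
  skip_if_not_installed("pROC")
  set.seed(54)
  truth <- rep(c(0, 1), each = 25)
  scores <- rnorm(50, mean = truth)
  cv <- binary_curves(scores, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(cv$roc_auc, ref, tolerance = 1e-12)
})

test_that("degenerate scores give the expected AUC extremes", {
  truth <- rep(c(0, 1), each = 5)
  expect_equal(binary_curves(truth, truth)$roc_auc, 1)        # perfect
  expect_equal(binary_curves(1 - truth, truth)$roc_auc, 0)    # inverted
  expect_equal(binary_curves(rep(0.5, 10), truth)$roc_auc, 0.5) # constant
  expect_error(binary_curves(1:5, rep(1, 5)), "both classes")
  expect_error(binary_curves(c(1, NA), c(0, 1)), "finite")
})

test_that("PR AUC is average precision and is 1 for a perfect ranking", {
  truth <- rep(c(0, 1), each = 5)
  expect_equal(binary_curves(truth, truth)$pr_auc, 1)
  # hand-computed: scores 4>3>2>1, labels 1,0,1,0 -> AP = (1 + 2/3)/2
  cv <- binary_curves(c(4, 3, 2, 1), c(1, 0, 1, 0))
  expect_equal(cv$pr_auc, (1 + 2 / 3) / 2)
})

test_that("balancing equalises classes without touching originals", {
  ds <- tiny_dataset(c(rep(0L, 10), rep(1L, 4)))
  out <- balance_by_augmentation(ds)
  expect_equal(sum(out$meta$label == 0), 10)
  expect_equal(sum(out$meta$label == 1), 10)
  expect_length(out$images, 20)
  # the original images and rows are untouched, in place
  expect_identical(out$images[1:14], ds$images)
  expect_identical(out$meta$augmented,
                   c(rep(FALSE, 14), rep(TRUE, 6)))
  # augmented rows carry minority-class labels
  expect_true(all(out$meta$label[out$meta$augmented] == 1L))
  # already-balanced data passes through unchanged
  bal <- tiny_dataset(rep(c(0L, 1L), 5))
  expect_identical(balance_by_augmentation(bal), bal)
  expect_error(balance_by_augmentation(tiny_dataset(rep(0L, 4))),
               "both classes")
})

test_that("signal-domain augmentation uses half-overlap windows when possible", {
  cfg <- tiny_sim_config()
  rec_a <- simulate_session(cfg, 1, 1, "alert")
  rec_d <- simulate_session(cfg, 1, 2, "drowsy")
  fir <- design_bandpass(0.1, 30, 128)
  rec_a <- apply_filter(rec_a, fir); rec_d <- apply_filter(rec_d, fir)
  segs <- c(segment_recording(rec_a, 20, "C3"),
            segment_recording(rec_d, 20, "C3")[1])   # 3 alert vs 1 drowsy
  ds <- segments_to_scalograms(segs, scales = default_scales(128, 8, 4, 30),
                               native_size = c(40, 32),
                               storage_size = c(24, 24),
                               input_size = c(12, 12))
  recs <- list("1.1" = rec_a, "1.2" = rec_d)
  out <- balance_by_augmentation(ds, recs, window = 20, channels = "C3")
  expect_equal(sum(out$meta$label == 1), sum(out$meta$label == 0))
  aug <- out$meta[out$meta$augmented, ]
  expect_true(all(aug$label == 1L))
  # offsets at odd half-window multiples (half-overlap re-windowing)
  expect_true(all(aug$start %% (10 * 128) == 0 &
                    (aug$start / (10 * 128)) %% 2 == 1))
})

test_that("pooled stratified split has the published proportions", {
  meta <- data.frame(label = rep(c(0L, 1L), each = 50),
                     subject = rep(1:10, 10))
  parts <- make_split(meta, split_spec(train_fraction = 0.7, seed = 4))
  expect_length(intersect(parts$train, parts$test), 0)
  expect_setequal(c(parts$train, parts$test), 1:100)
  expect_equal(sum(meta$label[parts$train] == 0), 35)
  expect_equal(sum(meta$label[parts$train] == 1), 35)
  # deterministic given the seed
  parts2 <- make_split(meta, split_spec(train_fraction = 0.7, seed = 4))
  expect_identical(parts[1:2], parts2[1:2])
})

test_that("leave-subjects-out split keeps subjects disjoint", {
  meta <- data.frame(label = rep(c(0L, 1L), 30),
                     subject = rep(1:6, each = 10))
  parts <- make_split(meta, split_spec(mode = "leave_subjects_out",
                                       train_fraction = 0.7, seed = 1))
  tr_subj <- unique(meta$subject[parts$train])
  te_subj <- unique(meta$subject[parts$test])
  expect_length(intersect(tr_subj, te_subj), 0)
  expect_gte(length(te_subj), 1)
  expect_gte(length(tr_subj), 1)
  expect_setequal(c(parts$train, parts$test), 1:60)
})

test_that("kernel comparison table reports gaps to the best kernel", {
  set.seed(55)
  n <- 60
  X <- rbind(matrix(rnorm(n, -1), n / 2, 2), matrix(rnorm(n, 1), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  tab <- run_kernel_comparison(X, y, train_idx = c(1:20, 31:50),
                               test_idx = c(21:30, 51:60),
                               kernels = c("rbf", "linear"), k = 3,
                               C_grid = c(1, 10), gamma_grid = c(0.4))
  expect_equal(nrow(tab), 2)
  expect_equal(min(tab$gap_to_best), 0)
  expect_equal(tab$gap_to_best, max(tab$accuracy) - tab$accuracy)
})

test_that("depth ablation marks infeasible depths instead of failing", {
  prob_images <- lapply(1:20, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  labels <- rep(c(0L, 1L), 10)
  for (i in which(labels == 1)) prob_images[[i]][1:4, , ] <-
    prob_images[[i]][1:4, , ] + 0.5
  tc <- train_config(epochs = 2, batch_size = 8, seed = 1,
                     early_stopping_patience = 2)
  tab <- run_depth_ablation(prob_images, labels, train_idx = 1:14,
                            test_idx = 15:20, depths = c(1, 10), tc = tc,
                            input_shape = c(8, 8, 3))
  expect_equal(nrow(tab), 2)
  expect_true(tab$feasible[tab$depth == 1])
  expect_false(tab$feasible[tab$depth == 10])
  expect_true(is.na(tab$accuracy[tab$depth == 10]))
})
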