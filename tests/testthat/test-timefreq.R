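# Morlet CWT and scalogram rendering / bicubic resizing.

test_that("fast CWT matches the direct inner-product oracle", {
  set.seed(11)
  fs <- 64; n <- 200
  x <- rnorm(n)
  scales <- frequency_to_scale(c(4, 6, 10, 16, 24), fs)
  fast <- cwt_morlet(x, scales, sampling_rate = fs)$coefficients
  direct <- cwt_morlet_direct(x, scales)
  expect_lt(max(abs(fast - direct)) / max(abs(direct)), 1e-3)
})

test_that("CWT is linear", {
  set.seed(12)
  fs <- 64; n <- 160
  scales <- frequency_to_scale(c(5, 10, 20), fs)
  x1 <- rnorm(n); x2 <- rnorm(n)
  w1 <- cwt_morlet(x1, scales, sampling_rate = fs)$coefficients
  w2 <- cwt_morlet(x2, scales, sampling_rate = fs)$coefficients
  w <- cwt_morlet(3 * x1 - 0.5 * x2, scales, sampling_rate = fs)$coefficients
  expect_equal(w, 3 * w1 - 0.5 * w2, tolerance = 1e-10)
})

test_that("CWT magnitude localises tones at their pseudo-frequency", {
  fs <- 128
  t <- (0:(fs * 8 - 1)) / fs
  scales <- default_scales(fs, n_scales = 48, fmin = 2, fmax = 30)
  for (f0 in c(6, 10, 20)) {
    g <- cwt_morlet(sin(2 * pi * f0 * t), scales, sampling_rate = fs)
    peak <- g$pseudo_frequencies[which.max(rowMeans(abs(g$coefficients)^2))]
    expect_equal(peak, f0, tolerance = 0.08 * f0)
  }
})

test_that("scale/frequency conversions invert each other", {
  fs <- 128
  f <- c(0.5, 1, 7.3, 30)
  expect_equal(scale_to_frequency(frequency_to_scale(f, fs), fs), f)
  # doubling the scale halves the frequency
  s <- frequency_to_scale(10, fs)
  expect_equal(scale_to_frequency(2 * s, fs), 5)
  expect_error(frequency_to_scale(0, fs), "positive")
  expect_error(scale_to_frequency(-1, fs), "positive")
})

test_that("default scale ladder spans 0.5-30 Hz with 64 rungs", {
  sc <- default_scales(128)
  expect_length(sc, 64)
  f <- scale_to_frequency(sc, 128)
  expect_equal(range(f), c(0.5, 30))
  expect_true(all(diff(sc) > 0))
  # log spacing: constant ratio
  expect_equal(sd(diff(log(sc))), 0, tolerance = 1e-12)
})

test_that("CWT rejects segments shorter than the wavelet support", {
  fs <- 128
  sc <- frequency_to_scale(0.5, fs)    # support ~ 6 * 244 samples
  expect_error(cwt_morlet(rnorm(fs), sc, sampling_rate = fs), "support")
  expect_error(cwt_morlet(numeric(0), 2, sampling_rate = fs), "empty")
  expect_error(cwt_morlet(rnorm(64), scales = numeric(0),
                          sampling_rate = fs), "empty")
})

test_that("cached kernel path returns identical results on repeat calls", {
  fs <- 64
  x <- sin(2 * pi * 8 * (0:255) / fs)
  sc <- frequency_to_scale(c(5, 8), fs)
  a <- cwt_morlet(x, sc, sampling_rate = fs)$coefficients
  b <- cwt_morlet(x, sc, sampling_rate = fs)$coefficients
  expect_identical(a, b)
})

test_that("bicubic resize reproduces constants, ramps, and the identity", {
  M <- matrix(0.37, 10, 12)
  expect_equal(drowsEEG:::resize_matrix_bicubic(M, 5, 7),
               matrix(0.37, 5, 7), tolerance = 1e-12)
  # cubic convolution reproduces linear functions exactly away from the
  # clamped edges: with pixel-centre alignment the i-th output of a 20 -> 10
  # resize samples 0-based source position 2*i - 1.5
  ramp <- outer(seq(0, 1, length.out = 20), seq(0, 2, length.out = 20), "+")
  r <- drowsEEG:::resize_matrix_bicubic(ramp, 10, 10)
  expect_equal(dim(r), c(10L, 10L))
  pos <- 2 * (2:9) - 1.5
  expected <- outer(pos / 19, 2 * pos / 19, "+")
  expect_equal(r[2:9, 2:9], expected, tolerance = 1e-10)
  A <- drowsEEG:::cubic_resize_matrix(16, 16)
  expect_equal(A, diag(16), tolerance = 1e-12)   # identity at equal size
  expect_equal(rowSums(drowsEEG:::cubic_resize_matrix(50, 13)), rep(1, 13))
})

test_that("render_scalogram yields an RGB image in [0,1] at the target size", {
  fs <- 128
  t <- (0:(fs * 8 - 1)) / fs
  g <- cwt_morlet(sin(2 * pi * 10 * t) + 0.1 * rnorm(length(t)),
                  default_scales(fs, 32, 2, 30), sampling_rate = fs)
  img <- render_scalogram(g, size = c(60, 40))
  expect_s3_class(img, "scalogram_image")
  expect_equal(dim(img$pixels), c(40, 60, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  small <- resize_image(img, c(16, 16))
  expect_equal(dim(small$pixels), c(16, 16, 3))
  expect_true(all(small$pixels >= 0 & small$pixels <= 1))
})

test_that("a constant-magnitude grid renders as a constant image", {
  g <- structure(list(coefficients = matrix(2 + 0i, 8, 30),
                      scales = 1:8, pseudo_frequencies = 8:1,
                      times = (0:29) / 10, sampling_rate = 10,
                      wavelet = list(family = "morlet"), source = NULL),
                 class = "scalogram_grid")
  img <- render_scalogram(g, size = c(20, 10))
  expect_equal(max(apply(img$pixels, 3, sd)), 0, tolerance = 1e-12)
})

test_that("segments_to_scalograms produces network-ready arrays + manifest", {
  fs <- 128
  rec <- simulate_session(tiny_sim_config(), 1, 2, "drowsy")
  segs <- segment_recording(rec, window = 15, channels = "C3")
  ds <- segments_to_scalograms(segs, scales = default_scales(fs, 16, 2, 30),
                               native_size = c(66, 54),
                               storage_size = c(32, 32),
                               input_size = c(16, 16))
  expect_s3_class(ds, "scalogram_dataset")
  expect_length(ds$images, 4)
  expect_equal(dim(ds$images[[1]]), c(16, 16, 3))
  expect_identical(ds$meta$label, rep(1L, 4))
  expect_false(any(ds$meta$augmented))
})

test_that("PNG export writes one image per segment", {
  fs <- 128
  rec <- simulate_session(tiny_sim_config(), 1, 1, "alert")
  segs <- segment_recording(rec, window = 30, channels = "C3")
  dir <- tempfile()
  segments_to_scalograms(segs, scales = default_scales(fs, 8, 4, 30),
                         native_size = c(40, 32), storage_size = c(24, 24),
                         input_size = c(12, 12), png_dir = dir)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_length(pngs, length(segs))
  px <- png::readPNG(file.path(dir, pngs[1]))
  expect_equal(dim(px)[1:2], c(24, 24))
})
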