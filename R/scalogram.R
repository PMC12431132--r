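# Scalogram rendering and bicubic image resizing.

# Keys cubic convolution kernel (a = -0.5, the conventional bicubic).
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Interpolation matrix mapping `src` samples onto `dst` samples with cubic
# convolution and clamped (replicated) edges. Rows sum to 1.
cubic_resize_matrix <- function(src, dst) {
  if (dst < 1 || src < 1) stop("non-positive image size")
  if (src == 1) return(matrix(1, nrow = dst, ncol = 1))
  # pixel-centre alignment, as in standard image resizing
  pos <- ((seq_len(dst) - 0.5) * src / dst) - 0.5
  A <- matrix(0, nrow = dst, ncol = src)
  for (i in seq_len(dst)) {
    base <- floor(pos[i])
    idx <- base + (-1:2)
    w <- cubic_kernel(pos[i] - idx)
    idx <- pmin(pmax(idx + 1, 1), src)    # clamp to edge
    for (j in 1:4) A[i, idx[j]] <- A[i, idx[j]] + w[j]
  }
  A / rowSums(A)
}

.resize_cache <- new.env(parent = emptyenv())
resize_matrix_cached <- function(src, dst) {
  key <- paste0(src, ">", dst)
  A <- .resize_cache[[key]]
  if (is.null(A)) {
    A <- cubic_resize_matrix(src, dst)
    .resize_cache[[key]] <- A
  }
  A
}

# Bicubic resize of a 2D matrix (separable; the more reducing axis first).
resize_matrix_bicubic <- function(M, height, width) {
  A <- resize_matrix_cached(nrow(M), height)
  B <- resize_matrix_cached(ncol(M), width)
  cost_rows_first <- height * nrow(M) * ncol(M) + height * ncol(M) * width
  cost_cols_first <- nrow(M) * ncol(M) * width + height * nrow(M) * width
  if (cost_rows_first <= cost_cols_first) {
    (A %*% M) %*% t(B)
  } else {
    A %*% (M %*% t(B))
  }
}

# 256-entry RGB lookup table for a fixed perceptually uniform colormap.
colormap_lut <- function(name = "viridis") {
  cols <- grDevices::hcl.colors(256, palette = name)
  t(grDevices::col2rgb(cols)) / 255
}

#' Render a scalogram grid as an RGB image
#'
#' Log-magnitude of the wavelet coefficients, min-max normalised per image
#' to \[0, 1\], mapped through a fixed perceptually uniform colormap. Time
#' runs along the horizontal axis; frequency along the vertical axis with
#' low frequencies at the bottom. No axes or annotations are drawn. A
#' degenerate (constant-magnitude) grid renders as a constant mid-colormap
#' image.
#'
#' @param grid A `scalogram_grid` from [cwt_morlet()].
#' @param colormap Palette name passed to [grDevices::hcl.colors()].
#' @param size `c(width, height)` of the rendered image in pixels
#'   (default the native 662 x 536).
#' @return An object of class `scalogram_image`: array `pixels`
#'   (height x width x 3) in \[0, 1\] plus a `render` descriptor and the
#'   source provenance.
#' @export
render_scalogram <- function(grid, colormap = "viridis",
                             size = c(662, 536)) {
  stopifnot(inherits(grid, "scalogram_grid"))
  mag <- abs(grid$coefficients)
  if (length(mag) == 0) stop("degenerate grid")
  # floor at a tiny fraction of the peak to keep the log finite
  eps <- max(mag) * 1e-8
  logmag <- log10(pmax(mag, max(eps, .Machine$double.xmin)))
  rng <- range(logmag)
  norm <- if (diff(rng) > 0) (logmag - rng[1]) / diff(rng)
          else matrix(0.5, nrow(logmag), ncol(logmag))
  # rows are scales in increasing scale = decreasing frequency order; with
  # row 1 at the top of the image that puts low frequencies at the bottom
  width <- size[1]; height <- size[2]
  if (width < 1 || height < 1) stop("non-positive target size")
  resized <- resize_matrix_bicubic(norm, height, width)
  resized <- pmin(pmax(resized, 0), 1)
  lut <- colormap_lut(colormap)
  idx <- matrix(as.integer(round(resized * 255)) + 1L,
                nrow = height, ncol = width)
  pixels <- array(0, dim = c(height, width, 3))
  for (c in 1:3) pixels[, , c] <- matrix(lut[idx, c], height, width)
  structure(list(
    pixels = pixels,
    source = grid$source,
    render = list(colormap = colormap, normalization = "minmax-log-magnitude",
                  native_size = c(width = width, height = height),
                  wavelet = grid$wavelet)
  ), class = "scalogram_image")
}

#' Bicubic resize of an RGB scalogram image
#'
#' Cubic-convolution interpolation per channel, with output clipped to
#' \[0, 1\]. The pipeline stores images at 256 x 256 and feeds the network at
#' 64 x 64 (a second bicubic resize at training time).
#'
#' @param img A `scalogram_image` or a height x width x 3 array.
#' @param target `c(width, height)` in pixels.
#' @return A `scalogram_image` at the target size.
#' @export
resize_image <- function(img, target = c(256, 256)) {
  px <- if (inherits(img, "scalogram_image")) img$pixels else img
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("expected a height x width x 3 image array")
  if (any(target < 1)) stop("non-positive target size")
  width <- target[1]; height <- target[2]
  out <- array(0, dim = c(height, width, 3))
  for (c in 1:3) {
    out[, , c] <- pmin(pmax(resize_matrix_bicubic(px[, , c], height, width),
                            0), 1)
  }
  if (inherits(img, "scalogram_image")) {
    img$pixels <- out
    img$render$size <- c(width = width, height = height)
    img
  } else {
    out
  }
}

#' Write a scalogram image to PNG
#' @param img A `scalogram_image`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scalogram_png <- function(img, path) {
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

#' Convert segments to network-ready scalogram images
#'
#' Runs the full image chain per segment: Morlet CWT, native-resolution
#' RGB render, bicubic resize to the storage size then to the network
#' input size.
#'
#' @param segments List of `eeg_segment` objects.
#' @param scales Wavelet scales (default [default_scales()]).
#' @param colormap Palette name.
#' @param native_size,storage_size,input_size `c(width, height)` of the
#'   rendered, stored and network-input images.
#' @param png_dir Optional directory; if given, storage-size PNGs and a
#'   manifest CSV are written there.
#' @return A `scalogram_dataset`: list with `images` (list of
#'   height x width x 3 arrays at `input_size`), `meta` (data.frame:
#'   subject, session, channel, start, label, augmented) and `params`.
#' @export
segments_to_scalograms <- function(segments, scales = NULL,
                                   colormap = "viridis",
                                   native_size = c(662, 536),
                                   storage_size = c(256, 256),
                                   input_size = c(64, 64),
                                   png_dir = NULL) {
  stopifnot(length(segments) >= 1)
  if (is.null(scales)) scales <- default_scales(segments[[1]]$sampling_rate)
  images <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    grid <- cwt_morlet(segments[[i]], scales = scales)
    img <- render_scalogram(grid, colormap = colormap, size = native_size)
    img <- resize_image(img, storage_size)
    if (!is.null(png_dir)) {
      if (!dir.exists(png_dir)) dir.create(png_dir, recursive = TRUE)
      write_scalogram_png(img, file.path(png_dir, sprintf("scal%05d.png", i)))
    }
    images[[i]] <- resize_image(img, input_size)$pixels
  }
  meta <- segment_manifest(segments)
  meta$augmented <- FALSE
  ds <- structure(list(images = images, meta = meta,
                       params = list(scales = scales, colormap = colormap,
                                     native_size = native_size,
                                     storage_size = storage_size,
                                     input_size = input_size)),
                  class = "scalogram_dataset")
  if (!is.null(png_dir))
    write.csv(meta, file.path(png_dir, "scalograms.csv"), row.names = FALSE)
  ds
}

#' @export
print.scalogram_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<scalogram_dataset> %d images (%dx%dx%d), %d drowsy / %d alert, %d augmented\n",
              length(x$images), d[1], d[2], d[3],
              sum(x$meta$label == 1), sum(x$meta$label == 0),
              sum(x$meta$augmented)))
  invisible(x)
}
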