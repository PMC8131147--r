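# Local gradient-orientation descriptors (SIFT-style) for scalp maps and
# other images. Each keypoint gets a spatial_bins^2 x n_orientations
# histogram of image-gradient orientations over a square support window,
# weighted by gradient magnitude. Descriptor magnitudes are kept
# unnormalized by default: for band-power topographies the absolute
# gradient scale *is* the discriminative signal (it is proportional to the
# band power), and classic SIFT contrast normalization would discard it.

#' Regular grid of keypoints over an image
#'
#' @param h,w Image size in pixels.
#' @param grid Keypoints per side (`grid^2` keypoints).
#' @param support Descriptor support side length; keypoints are inset so
#'   the window always fits inside the image.
#' @return `grid^2 x 2` matrix of (row, col) keypoint centers.
#' @export
grid_keypoints <- function(h, w, grid = 5L, support = 8L) {
  half <- support %/% 2L
  # inset by one extra pixel: gradients need a 1-pixel pad around the window
  rs <- round(seq(half + 1L, h - half - 1L, length.out = grid))
  cs <- round(seq(half + 1L, w - half - 1L, length.out = grid))
  as.matrix(expand.grid(row = rs, col = cs))
}

# Central-difference gradients on the window interior.
image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  if (h >= 3) gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' Gradient-orientation descriptor at one keypoint
#'
#' Histograms the gradient orientations in a `support x support` window
#' around the keypoint into `spatial_bins^2` spatial cells times
#' `n_orientations` orientation bins, weighting each pixel by its gradient
#' magnitude. A constant image therefore yields an all-zero descriptor.
#'
#' @param img Numeric image matrix.
#' @param keypoint `c(row, col)` center.
#' @param support Window side length (multiple of `spatial_bins`).
#' @param spatial_bins Spatial cells per side.
#' @param n_orientations Orientation bins over `[0, 2 pi)`.
#' @param normalize If `TRUE`, apply the classic SIFT contrast
#'   normalization (L2, clip at 0.2, renormalize); default `FALSE` keeps
#'   gradient magnitudes, which carry band-power information.
#' @return Numeric descriptor of length `spatial_bins^2 * n_orientations`.
#' @export
sift_descriptor <- function(img, keypoint, support = 8L, spatial_bins = 2L,
                            n_orientations = 8L, normalize = FALSE) {
  half <- support %/% 2L
  r0 <- keypoint[1] - half + 1L
  c0 <- keypoint[2] - half + 1L
  if (r0 < 2L || c0 < 2L || r0 + support > nrow(img) ||
      c0 + support > ncol(img))
    abort_input("keypoint support window falls outside the image")
  win <- img[(r0 - 1L):(r0 + support), (c0 - 1L):(c0 + support), drop = FALSE]
  # gradients on the padded window; interior support x support block is valid
  g <- image_gradients(win)
  gx <- g$gx[2:(support + 1L), 2:(support + 1L)]
  gy <- g$gy[2:(support + 1L), 2:(support + 1L)]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  obin <- pmin(floor(ang / (2 * pi) * n_orientations) + 1L, n_orientations)
  cell <- support %/% spatial_bins
  rows <- pmin((row(mag) - 1L) %/% cell + 1L, spatial_bins)
  cols <- pmin((col(mag) - 1L) %/% cell + 1L, spatial_bins)
  sbin <- (cols - 1L) * spatial_bins + rows
  desc <- numeric(spatial_bins^2 * n_orientations)
  idx <- (sbin - 1L) * n_orientations + obin
  for (i in seq_along(idx)) desc[idx[i]] <- desc[idx[i]] + mag[i]
  if (normalize) {
    nrm <- sqrt(sum(desc^2))
    if (nrm > 0) {
      desc <- pmin(desc / nrm, 0.2)
      desc <- desc / sqrt(sum(desc^2))
    }
  }
  desc
}

#' Build the M x N feature matrix for the BCN
#'
#' One descriptor row per keypoint. For EEG topographies the keypoints are
#' a fixed grid ([grid_keypoints()]); for facial images a precomputed
#' landmark set can be supplied instead. A matrix input (precomputed
#' landmark descriptors) is validated and passed through unchanged.
#'
#' @param x Image matrix, `topo_image`, or an already-built feature matrix.
#' @param keypoints `M x 2` (row, col) matrix; defaults to a grid.
#' @param grid Keypoints per side when defaulting.
#' @param support,spatial_bins,n_orientations,normalize Passed to
#'   [sift_descriptor()].
#' @return M x N numeric feature matrix.
#' @export
build_feature_matrix <- function(x, keypoints = NULL, grid = 5L,
                                 support = 8L, spatial_bins = 4L,
                                 n_orientations = 8L, normalize = FALSE) {
  if (inherits(x, "topo_image")) x <- x$pixels
  if (is.matrix(x) && is.null(keypoints) && !is.null(attr(x, "is_features")))
    return(x)
  img <- as_mat(x)
  if (is.null(keypoints))
    keypoints <- grid_keypoints(nrow(img), ncol(img), grid, support)
  t(apply(keypoints, 1L, function(kp)
    sift_descriptor(img, kp, support, spatial_bins, n_orientations, normalize)))
}
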