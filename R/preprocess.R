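# Orthogonal Daubechies-4 analysis filters (standard published constants);
# synthesis is the adjoint since the periodized transform is orthonormal.
db4_filters <- function() {
  lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
  hi <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
          -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
          -0.0328830116668852, -0.010597401785069032)
  list(lo = lo, hi = hi)
}

# One periodized analysis step: x (even length n) -> list(a, d) of length n/2.
# a[k] = sum_m lo[m] x[(2k + L/2 - m) mod n] (0-based), matching the usual
# periodization convention.
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(filt$lo)
  off <- L %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  k <- 0:(half - 1L)
  for (m in 0:(L - 1L)) {
    idx <- ((2L * k + off - m) %% n) + 1L
    a <- a + filt$lo[m + 1L] * x[idx]
    d <- d + filt$hi[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

# Adjoint (= inverse, orthonormal filters) of dwt_step.
idwt_step <- function(a, d, filt, n) {
  L <- length(filt$lo)
  off <- L %/% 2L
  x <- numeric(n)
  k <- 0:(length(a) - 1L)
  for (m in 0:(L - 1L)) {
    idx <- ((2L * k + off - m) %% n) + 1L
    contrib <- filt$lo[m + 1L] * a + filt$hi[m + 1L] * d
    # idx may repeat when n < L; accumulate safely
    for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + contrib[i]
  }
  x
}

# Multi-level periodized DWT. Returns list(approx, details = list(d1 finest
# first per position [[level]]...)); details stored coarsest-last like the
# usual wavedec ordering reversed -- here details[[j]] is the level-j detail
# (j = 1 finest).
wavedec_periodic <- function(x, level, filt = db4_filters()) {
  n <- length(x)
  if (level < 1) abort_input("decomposition level must be >= 1")
  if (n %% (2^level) != 0)
    abort_input("signal length must be divisible by 2^level for the periodized transform")
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, filt)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

waverec_periodic <- function(dec, filt = db4_filters()) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]], filt, 2L * length(a))
  }
  a
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# Denoise one channel: db4 wavedec, soft-threshold all detail levels,
# reconstruct. Universal threshold lambda = sigma * sqrt(2 log n) with sigma
# from the median absolute deviation of the finest-level details.
denoise_channel <- function(x, level, threshold = NULL) {
  dec <- wavedec_periodic(x, level)
  if (is.null(threshold)) {
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  dec$details <- lapply(dec$details, soft_threshold, lambda = threshold)
  waverec_periodic(dec)
}

#' Wavelet soft-threshold denoising
#'
#' Per channel: discrete wavelet decomposition (db4, periodized) to `level`,
#' soft-thresholding of every detail coefficient (shrink toward zero by
#' lambda, zeroing coefficients below it), and reconstruction. The default
#' threshold is the universal rule lambda = sigma * sqrt(2 log L) with sigma
#' estimated from the median absolute deviation of the finest detail level.
#'
#' @param raw A [raw_eeg()] object.
#' @param wavelet_name Currently only `"db4"`.
#' @param level Decomposition depth; the trial length must be divisible by
#'   `2^level`.
#' @param threshold_rule `"universal"` (default) or `"fixed"` (then
#'   `threshold` is used as lambda for every channel).
#' @param threshold Fixed lambda when `threshold_rule = "fixed"`; `0` makes
#'   the operation an identity up to reconstruction round-off.
#' @return A [raw_eeg()] of the same shape and sampling rate.
#' @export
denoise_wavelet_soft <- function(raw, wavelet_name = "db4", level = 4,
                                 threshold_rule = c("universal", "fixed"),
                                 threshold = NULL) {
  stopifnot(inherits(raw, "raw_eeg"))
  threshold_rule <- match.arg(threshold_rule)
  if (wavelet_name != "db4")
    abort_config("only the db4 wavelet is implemented")
  if (threshold_rule == "fixed" && !is_scalar_number(threshold))
    abort_config("threshold_rule = 'fixed' needs a numeric threshold")
  lam <- if (threshold_rule == "fixed") threshold else NULL
  out <- raw
  out$samples <- t(apply(raw$samples, 1L, denoise_channel,
                         level = level, threshold = lam))
  rownames(out$samples) <- rownames(raw$samples)
  out
}

#' Segment a trial into non-overlapping windows
#'
#' Produces `floor(duration / T)` segments of length `round(T *
#' sampling_rate)` samples in temporal order; a trailing remainder shorter
#' than one window is dropped. `1/T` is the frame rate the facial-expression
#' stream is aligned to.
#'
#' @param raw A [raw_eeg()].
#' @param T Segment duration in seconds (window must be at least 32 samples).
#' @return List of `eeg_segment` objects (fields `samples`, `duration`,
#'   `index`, `sampling_rate`).
#' @export
segment_eeg <- function(raw, T = 0.5) {
  stopifnot(inherits(raw, "raw_eeg"))
  if (!is_scalar_number(T) || T <= 0) abort_input("T must be positive")
  win <- round(T * raw$sampling_rate)
  if (win < 32) abort_input("T x sampling_rate must be at least 32 samples")
  n_seg <- floor(ncol(raw$samples) / win)
  lapply(seq_len(n_seg), function(i) {
    structure(list(
      samples = raw$samples[, ((i - 1L) * win + 1L):(i * win), drop = FALSE],
      duration = T,
      index = i,
      sampling_rate = raw$sampling_rate
    ), class = "eeg_segment")
  })
}

# Welch PSD, one-sided density: sum(psd) * df equals the mean-square power
# of the signal (up to windowing bias). Hann window, 50% overlap.
welch_psd <- function(x, fs, nperseg = min(length(x), 128L)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)
  U <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * U)
    scale2 <- rep(2, nf)
    scale2[1] <- 1
    if (nperseg %% 2L == 0L) scale2[nf] <- 1
    acc <- acc + p * scale2
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts),
       df = fs / nperseg)
}

#' Per-channel spectral band power of a segment
#'
#' Integrates the Welch power spectral density (Hann window, 50% overlap)
#' over a frequency band. Bands are half-open `[lo, hi)` so adjacent bands
#' partition the spectrum. The result is a mean-square power per channel
#' (uV^2); scaling the signal by k scales it by k^2.
#'
#' @param segment An `eeg_segment` from [segment_eeg()].
#' @param band Band name (`"alpha"`, `"beta"`, `"theta"`) or a numeric
#'   `c(lo, hi)` in Hz; the band must lie below Nyquist.
#' @param nperseg Welch window length (samples).
#' @return Object of class `band_power_vector`: list with `band` and
#'   `power` (named numeric, one nonnegative value per channel).
#' @export
band_power <- function(segment, band, nperseg = min(ncol(segment$samples), 128L)) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (is.character(band)) {
    band_name <- band
    edges <- eeg_bands()[[band]]
    if (is.null(edges)) abort_input("unknown band name")
  } else {
    band_name <- paste0(band, collapse = "-")
    edges <- as.numeric(band)
  }
  if (length(edges) != 2 || edges[1] >= edges[2])
    abort_input("band must be c(lo, hi) with lo < hi")
  if (edges[2] > segment$sampling_rate / 2)
    abort_input("band upper edge exceeds the Nyquist frequency")
  pw <- apply(segment$samples, 1L, function(x) {
    sp <- welch_psd(x, segment$sampling_rate, nperseg)
    keep <- sp$freq >= edges[1] & sp$freq < edges[2]
    sum(sp$psd[keep]) * sp$df
  })
  structure(list(band = band_name, power = pw), class = "band_power_vector")
}

#' Interpolate electrode values onto a scalp image
#'
#' Shepard inverse-distance-weighted interpolation of per-electrode values
#' onto an `resolution x resolution` pixel grid over the unit disc. Pixels
#' outside the scalp mask are zero; the pixel nearest each electrode is
#' pinned to that electrode's value, and every interior pixel lies within
#' the range of the electrode values.
#'
#' @param values A `band_power_vector` or a plain numeric vector (one value
#'   per electrode).
#' @param positions n x 2 matrix of unit-disc electrode coordinates
#'   (defaults to the [montage_32()] layout).
#' @param resolution Image side length in pixels.
#' @param idw_power Shepard weight exponent.
#' @return Object of class `topo_image`: list with `pixels` (H x W, zero
#'   outside the mask), `mask` (logical H x W), and `electrode_pixels`
#'   (n x 2 row/col indices of each electrode's nearest pixel).
#' @export
topo_image <- function(values, positions = NULL, resolution = 32,
                       idw_power = 2) {
  if (inherits(values, "band_power_vector")) values <- values$power
  values <- as.numeric(values)
  if (is.null(positions)) {
    m <- montage_32()
    positions <- cbind(m$x, m$y)
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(values))
    abort_input("one position per electrode value is required")
  if (anyDuplicated(round(positions, 10)))
    abort_input("duplicate electrode positions")
  if (any(rowSums(positions^2) > 1 + 1e-9))
    abort_input("electrode positions must lie inside the unit disc")
  H <- resolution
  gx <- seq(-1, 1, length.out = H)
  gy <- seq(1, -1, length.out = H) # row 1 = top of scalp (nose)
  px <- matrix(rep(gx, each = H), H, H)         # column coordinate
  py <- matrix(rep(gy, times = H), H, H)        # row coordinate
  mask <- px^2 + py^2 <= 1
  num <- matrix(0, H, H)
  den <- matrix(0, H, H)
  for (i in seq_along(values)) {
    d2 <- (px - positions[i, 1])^2 + (py - positions[i, 2])^2
    w <- 1 / pmax(d2, 1e-12)^(idw_power / 2)
    num <- num + w * values[i]
    den <- den + w
  }
  pixels <- num / den
  pixels[!mask] <- 0
  # pin each electrode's nearest in-mask pixel to its exact value
  epix <- matrix(0L, length(values), 2)
  for (i in seq_along(values)) {
    d2 <- (px - positions[i, 1])^2 + (py - positions[i, 2])^2
    d2[!mask] <- Inf
    j <- which.min(d2)
    r <- ((j - 1L) %% H) + 1L
    cc <- ((j - 1L) %/% H) + 1L
    pixels[r, cc] <- values[i]
    epix[i, ] <- c(r, cc)
  }
  structure(list(pixels = pixels, mask = mask, electrode_pixels = epix),
            class = "topo_image")
}

#' EEG trial to per-segment band topography sequence
#'
#' The full EEG visual branch: optional wavelet denoising, segmentation into
#' windows of `T` seconds, per-segment alpha/beta/theta band powers, and
#' scalp-map rendering of each band-power vector.
#'
#' @param raw A [raw_eeg()].
#' @param T Segment duration, seconds.
#' @param bands Named list of band edges (defaults to [eeg_bands()]).
#' @param resolution Topography side length in pixels.
#' @param denoise If `TRUE`, apply [denoise_wavelet_soft()] first.
#' @param denoise_level Wavelet depth when denoising.
#' @return List with one element per segment, each a list of `topo_image`
#'   objects named by band, with the raw band-power matrix attached as
#'   attribute `band_power` (bands x channels).
#' @export
eeg_topo_sequence <- function(raw, T = 0.5, bands = eeg_bands(),
                              resolution = 32, denoise = FALSE,
                              denoise_level = 4) {
  if (denoise) raw <- denoise_wavelet_soft(raw, level = denoise_level)
  segs <- segment_eeg(raw, T)
  pos <- raw$positions
  lapply(segs, function(sg) {
    # one PSD per channel, integrated over every band
    bp_mat <- t(apply(sg$samples, 1L, function(x) {
      sp <- welch_psd(x, sg$sampling_rate)
      vapply(bands, function(ed)
        sum(sp$psd[sp$freq >= ed[1] & sp$freq < ed[2]]) * sp$df, 0)
    }))
    imgs <- lapply(seq_along(bands), function(j)
      topo_image(bp_mat[, j], pos, resolution))
    names(imgs) <- names(bands)
    attr(imgs, "band_power") <- t(bp_mat)
    imgs
  })
}
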