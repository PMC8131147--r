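# Wavelet denoising, segmentation, band power and scalp topographies.

test_that("periodized db4 transform matches reference coefficients and inverts exactly", {
  # decomposition of sin(1:16) + 0.1*(1:16) at level 2, periodization mode;
  # expected values computed once with an independent reference DWT
  x <- sin(1:16) + 0.1 * (1:16)
  dec <- emofuse:::wavedec_periodic(x, 2)
  expect_equal(dec$approx,
               c(1.762354199953, 3.813484243376, 0.041954195421, 2.00609944259),
               tolerance = 1e-9)
  expect_equal(dec$details[[2]],
               c(-0.580512188811, -0.162806003575, 1.438758387541, -0.610373612544),
               tolerance = 1e-9)
  expect_equal(dec$details[[1]],
               c(-0.338156965701, 0.287914150011, -0.011334413795, -0.292385404855,
                 0.254684936361, 0.080412743689, -0.368348350219, 0.472993289025),
               tolerance = 1e-9)
  expect_equal(emofuse:::waverec_periodic(dec), x, tolerance = 1e-12)
})

test_that("soft-threshold denoising: identity at lambda 0, zeros stay zero, noise shrinks", {
  mont <- montage_32()
  set.seed(5)
  n <- 256
  clean <- matrix(rep(sin(2 * pi * 6 * (1:n) / 128), each = 32), 32, n,
                  byrow = FALSE)
  clean <- t(replicate(32, sin(2 * pi * 6 * (1:n) / 128)))
  noise <- matrix(rnorm(32 * n, sd = sqrt(mean(clean[1, ]^2))), 32, n) # SNR 0 dB
  raw <- raw_eeg(clean + noise, 128, mont)

  ident <- denoise_wavelet_soft(raw, level = 4, threshold_rule = "fixed",
                                threshold = 0)
  expect_lt(max(abs(ident$samples - raw$samples)) / max(abs(raw$samples)), 1e-8)

  zeros <- denoise_wavelet_soft(raw_eeg(matrix(0, 32, n), 128, mont), level = 4)
  expect_true(all(zeros$samples == 0))

  den <- denoise_wavelet_soft(raw, level = 4)
  resid_in <- mean((raw$samples - clean)^2)
  resid_out <- mean((den$samples - clean)^2)
  expect_lt(resid_out, resid_in)

  expect_error(denoise_wavelet_soft(raw, level = 10),
               class = "emofuse_input_error")
})

test_that("segmentation tiles the trial and drops the remainder", {
  mont <- montage_32()
  fs <- 128
  raw <- raw_eeg(matrix(rnorm(32 * fs * 10), 32), fs, mont)
  segs <- segment_eeg(raw, 0.5)
  expect_length(segs, 20)
  raw2 <- raw_eeg(matrix(rnorm(32 * round(fs * 10.3)), 32), fs, mont)
  segs2 <- segment_eeg(raw2, 0.5)
  expect_length(segs2, 20)
  # concatenating segments reproduces the first 10 s exactly
  rebuilt <- do.call(cbind, lapply(segs2, `[[`, "samples"))
  expect_identical(unname(rebuilt), unname(raw2$samples[, 1:(20 * 64)]))
  expect_error(segment_eeg(raw, -1), class = "emofuse_input_error")
})

test_that("band power matches the Parseval oracle and scales quadratically", {
  mont <- montage_32()
  fs <- 128
  x <- sin(2 * pi * 10 * (1:(2 * fs)) / fs)
  raw <- raw_eeg(matrix(rep(x, each = 32), 32, byrow = FALSE), fs, mont)
  raw$samples <- t(replicate(32, x))
  seg <- segment_eeg(raw, 2)[[1]]

  total <- oracle_total_energy(x)
  a <- band_power(seg, "alpha")$power[1]
  b <- band_power(seg, "beta")$power[1]
  th <- band_power(seg, "theta")$power[1]
  expect_lt(abs(a - total) / total, 0.05)
  expect_lt(b / total, 0.02)
  expect_lt(th / total, 0.02)

  # agreement with an independent direct-DFT oracle on a noisy signal
  set.seed(2)
  y <- x + rnorm(length(x), sd = 0.3)
  segy <- seg; segy$samples[1, ] <- y
  ora <- oracle_band_energy(y, fs, 8, 13)
  est <- band_power(segy, "alpha", nperseg = length(y))$power[1]
  expect_lt(abs(est - ora) / ora, 0.15)

  # quadratic amplitude scaling, zero signal, Nyquist validation
  seg2 <- seg; seg2$samples <- 2 * seg$samples
  expect_equal(band_power(seg2, "alpha")$power, 4 * band_power(seg, "alpha")$power,
               tolerance = 1e-6)
  seg0 <- seg; seg0$samples[] <- 0
  expect_true(all(band_power(seg0, "alpha")$power == 0))
  expect_error(band_power(seg, c(30, 100)), class = "emofuse_input_error")
})

test_that("topographic interpolation is exact at electrodes and bounded", {
  m <- montage_32()
  pos <- cbind(m$x, m$y)
  const <- topo_image(rep(3.5, 32), pos)
  expect_true(all(abs(const$pixels[const$mask] - 3.5) < 1e-9))
  expect_true(all(const$pixels[!const$mask] == 0))

  v <- rep(0, 32); v[7] <- 2
  ti <- topo_image(v, pos)
  peak <- ti$electrode_pixels[7, ]
  expect_equal(ti$pixels[peak[1], peak[2]], 2, tolerance = 1e-9)
  expect_equal(which.max(ti$pixels), (peak[2] - 1) * nrow(ti$pixels) + peak[1])

  set.seed(3)
  vals <- runif(32, 1, 5)
  ti2 <- topo_image(vals, pos)
  inside <- ti2$pixels[ti2$mask]
  expect_true(all(inside >= min(vals) - 1e-9 & inside <= max(vals) + 1e-9))

  dup <- pos; dup[2, ] <- dup[1, ]
  expect_error(topo_image(vals, dup), class = "emofuse_input_error")
})

test_that("pipeline composition shows frontal beta dominance at high arousal", {
  cfg <- synth_config(n_trials = 50, trial_duration = 1, seed = 303)
  frontal <- which(montage_32()$frontal)
  hits_hi <- 0; hits_lo <- 0
  n_tr <- 25
  for (i in seq_len(n_tr)) {
    for (al in c(0, 2)) {
      tr <- generate_eeg_trial(cfg, emotion_label(al, 1), 4000 + 2 * i + al)
      seq1 <- eeg_topo_sequence(tr, T = 0.5, resolution = 16)
      beta_f <- mean(vapply(seq1, function(s) {
        idx <- s$beta$electrode_pixels[frontal, ]
        mean(s$beta$pixels[idx])
      }, 0))
      alpha_f <- mean(vapply(seq1, function(s) {
        idx <- s$alpha$electrode_pixels[frontal, ]
        mean(s$alpha$pixels[idx])
      }, 0))
      if (al == 2 && beta_f > alpha_f) hits_hi <- hits_hi + 1
      if (al == 0 && alpha_f > beta_f) hits_lo <- hits_lo + 1
    }
  }
  expect_gte(hits_hi / n_tr, 0.8)
  expect_gte(hits_lo / n_tr, 0.8)
})
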