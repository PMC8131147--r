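# Synthetic paired EEG / face-feature generator.

test_that("label and config validation reject out-of-range values", {
  expect_error(emotion_label(3, 0), class = "emofuse_input_error")
  expect_error(emotion_label(0, -1), class = "emofuse_input_error")
  expect_error(synth_config(n_trials = 0), class = "emofuse_config_error")
  expect_error(synth_config(sampling_rate = 50), class = "emofuse_config_error")
  bad_map <- list(`0` = c(alpha = -1, beta = 1, theta = 1),
                  `1` = c(alpha = 1, beta = 1, theta = 1),
                  `2` = c(alpha = 1, beta = 1, theta = 1))
  expect_error(synth_config(band_power_map = bad_map),
               class = "emofuse_config_error")
})

test_that("EEG trials are deterministic and single-band maps stay in band", {
  alpha_only <- list(`0` = c(alpha = 1, beta = 0, theta = 0),
                     `1` = c(alpha = 1, beta = 0, theta = 0),
                     `2` = c(alpha = 1, beta = 0, theta = 0))
  cfg <- synth_config(n_trials = 2, noise_sd = 0, band_power_map = alpha_only,
                      frontal_beta_gain = 1, trial_duration = 2, seed = 4)
  lab <- emotion_label(1, 1)
  tr1 <- generate_eeg_trial(cfg, lab, 99)
  tr2 <- generate_eeg_trial(cfg, lab, 99)
  expect_identical(tr1$samples, tr2$samples)
  # periodogram energy outside 8-13 Hz is negligible (finite-window
  # leakage of off-bin tones accounts for the rest)
  for (ch in c(1, 17, 32)) {
    x <- tr1$samples[ch, ]
    total <- oracle_total_energy(x)
    inband <- oracle_band_energy(x, cfg$sampling_rate, 8, 13)
    expect_gt(inband / total, 0.95)
  }
})

test_that("beta/alpha power ratio rises with arousal (Welch oracle)", {
  cfg <- synth_config(n_trials = 2, trial_duration = 2, seed = 9)
  ratios <- vapply(0:2, function(al) {
    tr <- generate_eeg_trial(cfg, emotion_label(al, 1), 1234 + al)
    mean(vapply(seq_len(8), function(ch) {
      x <- tr$samples[ch, ]
      oracle_band_energy(x, cfg$sampling_rate, 13, 30) /
        oracle_band_energy(x, cfg$sampling_rate, 8, 13)
    }, 0))
  }, 0)
  expect_true(ratios[1] < ratios[2] && ratios[2] < ratios[3])
})

test_that("noise-free channels concentrate >= 95% energy in the union of bands", {
  cfg <- synth_config(n_trials = 2, noise_sd = 0, trial_duration = 2, seed = 5)
  for (al in 0:2) {
    tr <- generate_eeg_trial(cfg, emotion_label(al, 0), 31 + al)
    for (ch in c(1, 16, 32)) {
      x <- tr$samples[ch, ]
      frac <- oracle_band_energy(x, cfg$sampling_rate, 4, 30) /
        oracle_total_energy(x)
      expect_gt(frac, 0.95)
    }
  }
})

test_that("face sequences are deterministic, valence-linked, and null at zero effect", {
  cfg <- synth_config(n_trials = 2, trial_duration = 2, seed = 12,
                      valence_effect_size = 2)
  lab <- emotion_label(0, 2)
  f1 <- generate_face_sequence(cfg, lab, 7)
  f2 <- generate_face_sequence(cfg, lab, 7)
  expect_identical(f1, f2)
  expect_length(f1, floor(cfg$trial_duration / cfg$segment_duration))

  # large effect: nearest-centroid oracle on flattened matrices > 90%
  n <- 300
  labs <- rep(0:2, length.out = n)
  X <- t(vapply(seq_len(n), function(i) {
    as.vector(generate_face_sequence(cfg, emotion_label(0, labs[i]), 1000 + i)[[1]])
  }, numeric(cfg$face_keypoints * cfg$face_dims)))
  centroids <- t(vapply(0:2, function(v) colMeans(X[labs == v, ]), X[1, ]))
  pred <- apply(X, 1, function(r) which.min(rowSums((centroids - rep(r, each = 3))^2)) - 1)
  expect_gt(mean(pred == labs), 0.9)

  # zero effect: class-conditional means agree within sampling error
  cfg0 <- synth_config(n_trials = 2, seed = 12, valence_effect_size = 0)
  m_by_class <- vapply(0:2, function(v) {
    mean(vapply(1:30, function(i)
      mean(generate_face_sequence(cfg0, emotion_label(0, v), 500 + i)[[1]]), 0))
  }, 0)
  expect_lt(max(m_by_class) - min(m_by_class), 0.05)
})

test_that("datasets are balanced, replayable from the manifest, and serializable", {
  cfg <- synth_config(n_trials = 9, trial_duration = 2, seed = 21)
  ds <- generate_dataset(cfg)
  tab <- table(ds$manifest$arousal, ds$manifest$valence)
  expect_true(all(tab == 1))

  cfg10 <- synth_config(n_trials = 10, trial_duration = 2, seed = 21)
  tab10 <- table(generate_dataset(cfg10)$manifest$arousal,
                 generate_dataset(cfg10)$manifest$valence)
  expect_lte(max(tab10) - min(tab10), 1)

  # manifest replay regenerates the identical dataset
  ds2 <- replay_dataset(cfg, ds$manifest)
  expect_identical(ds$trials[[5]]$eeg$samples, ds2$trials[[5]]$eeg$samples)
  expect_identical(ds$trials[[5]]$face, ds2$trials[[5]]$face)

  # full write/read round trip through plain-text files
  dir <- tempfile("emofuse_ds")
  write_dataset(ds, dir)
  ds3 <- read_dataset(dir)
  expect_equal(ds3$trials[[3]]$eeg$samples, ds$trials[[3]]$eeg$samples,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ds3$manifest$arousal, ds$manifest$arousal)
  unlink(dir, recursive = TRUE)
})

test_that("arousal level and frontal beta/alpha ratio share positive mutual information", {
  cfg <- synth_config(n_trials = 300, trial_duration = 2, seed = 77)
  ds <- generate_dataset(cfg)
  frontal <- which(montage_32()$frontal)
  ratio <- vapply(ds$trials, function(tr) {
    x <- tr$eeg$samples[frontal[1], ]
    oracle_band_energy(x, cfg$sampling_rate, 13, 30) /
      oracle_band_energy(x, cfg$sampling_rate, 8, 13)
  }, 0)
  levels_r <- cut(ratio, stats::quantile(ratio, c(0, 1/3, 2/3, 1)),
                  include.lowest = TRUE)
  joint <- table(ds$manifest$arousal, levels_r) / length(ratio)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (joint[i, j] > 0) mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  expect_gt(mi, 0.05)
})
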