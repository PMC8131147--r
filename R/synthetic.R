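#' Conventional EEG frequency band edges
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. Band intervals are treated as
#' half-open, `[lo, hi)`, so adjacent bands never double-count a frequency
#' bin.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Construct an arousal/valence emotion label
#'
#' Both dimensions are discretised to three levels (0 = low, 1 = medium,
#' 2 = high), the granularity used when 1-9 self-assessment ratings are
#' binned by numerical size.
#'
#' @param arousal,valence Integer level in `{0, 1, 2}`.
#' @return An object of class `emotion_label`.
#' @export
emotion_label <- function(arousal, valence) {
  for (v in c(arousal, valence)) {
    if (!is_scalar_number(v) || v != round(v) || v < 0 || v > 2)
      abort_input("arousal and valence levels must be integers in {0, 1, 2}")
  }
  structure(list(arousal = as.integer(arousal), valence = as.integer(valence)),
            class = "emotion_label")
}

default_band_power_map <- function() {
  # Relative band powers (uV^2) per arousal level: beta rises and alpha
  # falls with activation, theta flat. Ratios chosen to give a clearly
  # monotone beta/alpha contrast; the literature motivates the direction of
  # the effect, not its size.
  list(
    `0` = c(alpha = 1.2, beta = 0.3, theta = 0.6),
    `1` = c(alpha = 0.8, beta = 0.8, theta = 0.6),
    `2` = c(alpha = 0.4, beta = 1.6, theta = 0.6)
  )
}

#' Configuration for the synthetic paired EEG/expression generator
#'
#' The generator emulates the statistical skeleton of a dimensional-affect
#' recording session: 32-channel EEG whose alpha/beta/theta band powers are
#' driven by a latent arousal level (beta dominates at high activation,
#' alpha at low, with an extra beta gain over frontal electrodes), paired
#' with per-frame facial feature matrices whose mean pattern is driven by
#' the valence level.
#'
#' @param n_trials Number of paired trials.
#' @param sampling_rate EEG sampling rate, Hz (must exceed 60 Hz so the beta
#'   band lies below Nyquist).
#' @param trial_duration Trial length, seconds.
#' @param segment_duration Segment length T, seconds; `1/T` is the matched
#'   face frame rate.
#' @param band_power_map Named list (`"0"`, `"1"`, `"2"`) of per-arousal
#'   `c(alpha, beta, theta)` band powers, uV^2.
#' @param frontal_beta_gain Multiplier (>= 1) applied to the beta-wave
#'   amplitude on frontal electrodes.
#' @param noise_sd Additive white-noise standard deviation, uV.
#' @param valence_effect_size Scale of the valence-dependent mean pattern in
#'   the face feature matrices (noise sd is 1).
#' @param face_keypoints,face_dims Rows (keypoints) and columns (descriptor
#'   dimensions) of each face feature matrix.
#' @param seed Root seed; every random draw in the generator derives from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_trials = 300,
                         sampling_rate = 128,
                         trial_duration = 5,
                         segment_duration = 0.5,
                         band_power_map = default_band_power_map(),
                         frontal_beta_gain = 1.5,
                         noise_sd = 0.5,
                         valence_effect_size = 1,
                         face_keypoints = 12,
                         face_dims = 16,
                         seed = 1) {
  if (!is_scalar_number(n_trials) || n_trials < 1)
    abort_config("n_trials must be a positive count")
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 60)
    abort_config("sampling_rate must exceed 60 Hz (2 x 30 Hz beta edge)")
  if (!is_scalar_number(trial_duration) || trial_duration <= 0)
    abort_config("trial_duration must be positive")
  if (!is_scalar_number(segment_duration) || segment_duration <= 0)
    abort_config("segment_duration must be positive")
  if (!is.list(band_power_map) ||
      !all(c("0", "1", "2") %in% names(band_power_map)))
    abort_config("band_power_map needs entries for arousal levels 0, 1, 2")
  for (bp in band_power_map) {
    if (length(bp) != 3 || any(!is.finite(bp)) || any(bp < 0) ||
        !all(c("alpha", "beta", "theta") %in% names(bp)))
      abort_config("each band_power_map entry must be c(alpha, beta, theta) >= 0")
  }
  if (!is_scalar_number(frontal_beta_gain) || frontal_beta_gain < 1)
    abort_config("frontal_beta_gain must be >= 1")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    abort_config("noise_sd must be >= 0")
  if (!is_scalar_number(valence_effect_size) || valence_effect_size < 0)
    abort_config("valence_effect_size must be >= 0")
  structure(list(
    n_trials = as.integer(n_trials),
    sampling_rate = sampling_rate,
    trial_duration = trial_duration,
    segment_duration = segment_duration,
    band_power_map = band_power_map,
    frontal_beta_gain = frontal_beta_gain,
    noise_sd = noise_sd,
    valence_effect_size = valence_effect_size,
    face_keypoints = as.integer(face_keypoints),
    face_dims = as.integer(face_dims),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Construct a raw EEG object
#'
#' @param samples Channels x time numeric matrix, uV.
#' @param sampling_rate Sampling rate, Hz.
#' @param montage Electrode data frame (`name`, `x`, `y`); defaults to
#'   [montage_32()]. Row count must match `nrow(samples)`.
#' @return An object of class `raw_eeg` with fields `samples`,
#'   `sampling_rate`, `electrode_names`, `positions`.
#' @export
raw_eeg <- function(samples, sampling_rate, montage = montage_32()) {
  samples <- as.matrix(samples)
  if (nrow(samples) != nrow(montage))
    abort_input("channel count must match the montage")
  if (any(!is.finite(samples))) abort_input("EEG samples must all be finite")
  if (!is_scalar_number(sampling_rate) || sampling_rate < 64)
    abort_input("sampling_rate must be >= 64 Hz")
  if (anyDuplicated(montage$name)) abort_input("electrode names must be unique")
  rownames(samples) <- montage$name
  structure(list(
    samples = samples,
    sampling_rate = sampling_rate,
    electrode_names = montage$name,
    positions = cbind(x = montage$x, y = montage$y)
  ), class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

# Sum of `n_osc` random-phase sinusoids with frequencies uniform inside the
# band interior (1 Hz margin, so finite-window spectral estimates keep the
# energy in-band), scaled so the expected mean-square power equals `power`.
band_oscillation <- function(n_samples, fs, band, power, n_osc = 3) {
  t <- seq_len(n_samples) / fs
  amp <- sqrt(2 * power / n_osc)
  margin <- min(1, diff(band) / 4)
  x <- numeric(n_samples)
  for (k in seq_len(n_osc)) {
    f <- stats::runif(1, band[1] + margin, band[2] - margin)
    ph <- stats::runif(1, 0, 2 * pi)
    x <- x + amp * sin(2 * pi * f * t + ph)
  }
  x
}

#' Generate one synthetic EEG trial
#'
#' Each channel is a sum of band-limited oscillations (theta 4-8, alpha
#' 8-13, beta 13-30 Hz) whose mean-square powers follow
#' `config$band_power_map[[arousal]]`, plus white Gaussian noise. The beta
#' amplitude is multiplied by `frontal_beta_gain` on the frontal electrode
#' group, reproducing the frontal beta development that accompanies rising
#' emotional activation.
#'
#' @param config A [synth_config()].
#' @param label An [emotion_label()].
#' @param trial_seed Integer seed; fixing it makes the trial bit-identical
#'   across calls.
#' @return A [raw_eeg()] object.
#' @export
generate_eeg_trial <- function(config, label, trial_seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!inherits(label, "emotion_label"))
    abort_input("label must be an emotion_label")
  montage <- montage_32()
  n <- round(config$trial_duration * config$sampling_rate)
  powers <- config$band_power_map[[as.character(label$arousal)]]
  bands <- eeg_bands()
  with_seed(trial_seed, {
    samples <- matrix(0, nrow(montage), n)
    for (ch in seq_len(nrow(montage))) {
      x <- numeric(n)
      for (bn in names(bands)) {
        p <- powers[[bn]]
        if (bn == "beta" && montage$frontal[ch])
          p <- p * config$frontal_beta_gain^2  # amplitude gain => power gain^2
        if (p > 0)
          x <- x + band_oscillation(n, config$sampling_rate, bands[[bn]], p)
      }
      if (config$noise_sd > 0)
        x <- x + stats::rnorm(n, sd = config$noise_sd)
      samples[ch, ] <- x
    }
    raw_eeg(samples, config$sampling_rate, montage)
  })
}

face_class_pattern <- function(config, valence_level) {
  # Class-conditional mean pattern; depends only on the root seed so it is
  # shared by all trials of the same valence level.
  with_seed(derive_seed(config$seed, 9000 + valence_level), {
    matrix(stats::rnorm(config$face_keypoints * config$face_dims),
           config$face_keypoints, config$face_dims)
  })
}

#' Generate a synthetic facial feature-matrix sequence
#'
#' One M x N feature matrix per frame at frame rate `1/segment_duration`
#' (so the sequence is time-aligned with the EEG segmentation). Each frame
#' equals `valence_effect_size` times a valence-specific mean pattern plus
#' unit-variance Gaussian noise.
#'
#' @inheritParams generate_eeg_trial
#' @return List of `face_keypoints` x `face_dims` matrices, one per frame.
#' @export
generate_face_sequence <- function(config, label, trial_seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!inherits(label, "emotion_label"))
    abort_input("label must be an emotion_label")
  n_frames <- floor(config$trial_duration / config$segment_duration)
  pattern <- config$valence_effect_size * face_class_pattern(config, label$valence)
  with_seed(trial_seed, {
    lapply(seq_len(n_frames), function(i) {
      pattern + matrix(stats::rnorm(length(pattern)),
                       nrow(pattern), ncol(pattern))
    })
  })
}

balanced_labels <- function(n_trials) {
  # Round-robin over the 3x3 arousal x valence grid: cell counts never
  # differ by more than one.
  grid <- expand.grid(arousal = 0:2, valence = 0:2)
  idx <- ((seq_len(n_trials) - 1) %% 9) + 1
  data.frame(arousal = grid$arousal[idx], valence = grid$valence[idx])
}

#' Generate a paired synthetic dataset
#'
#' Labels are assigned round-robin over the 3 x 3 arousal/valence grid so
#' cell counts are as balanced as `n_trials` allows. All randomness derives
#' from `config$seed`; the manifest records the per-trial child seeds so any
#' trial (or the whole set) can be regenerated exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_dataset` with `trials` (each a list with
#'   `eeg`, `face`, `label`), `manifest` (data frame: trial, arousal,
#'   valence, eeg_seed, face_seed) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  labs <- balanced_labels(config$n_trials)
  manifest <- data.frame(
    trial = seq_len(config$n_trials),
    arousal = labs$arousal,
    valence = labs$valence,
    eeg_seed = vapply(seq_len(config$n_trials),
                      function(i) derive_seed(config$seed, 2 * i), 0),
    face_seed = vapply(seq_len(config$n_trials),
                       function(i) derive_seed(config$seed, 2 * i + 1), 0)
  )
  structure(list(
    trials = replay_trials(config, manifest),
    manifest = manifest,
    config = config
  ), class = "synth_dataset")
}

replay_trials <- function(config, manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    lab <- emotion_label(manifest$arousal[i], manifest$valence[i])
    list(
      eeg = generate_eeg_trial(config, lab, manifest$eeg_seed[i]),
      face = generate_face_sequence(config, lab, manifest$face_seed[i]),
      label = lab
    )
  })
}

#' Regenerate a dataset from its manifest
#'
#' @param config The [synth_config()] the manifest was produced under.
#' @param manifest A manifest data frame from [generate_dataset()].
#' @return A `synth_dataset` identical to the original.
#' @export
replay_dataset <- function(config, manifest) {
  structure(list(
    trials = replay_trials(config, manifest),
    manifest = manifest,
    config = config
  ), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d paired trials (EEG %g Hz, %g s; face %d x %d @ %g fps)\n",
              length(x$trials), x$config$sampling_rate, x$config$trial_duration,
              x$config$face_keypoints, x$config$face_dims,
              1 / x$config$segment_duration))
  invisible(x)
}

#' Write / read a synthetic dataset as plain-text files
#'
#' The on-disk layout is `manifest.csv`, `config.json`, and per-trial CSV
#' files under `eeg/` (channels x samples) and `face/` (one file per frame).
#'
#' @param dataset A `synth_dataset`.
#' @param dir Target directory (created if missing).
#' @return `dir` (write) or a `synth_dataset` (read).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(file.path(dir, "eeg"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "face"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$config)
  # named vectors serialize as arrays; keep the band names as object keys
  cfg$band_power_map <- lapply(cfg$band_power_map, as.list)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    utils::write.table(tr$eeg$samples,
                       file.path(dir, "eeg", sprintf("trial_%04d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    for (f in seq_along(tr$face)) {
      utils::write.table(tr$face[[f]],
                         file.path(dir, "face",
                                   sprintf("trial_%04d_frame_%02d.csv", i, f)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  bpm <- lapply(cfg$band_power_map, function(v) unlist(v))
  config <- synth_config(
    n_trials = cfg$n_trials, sampling_rate = cfg$sampling_rate,
    trial_duration = cfg$trial_duration,
    segment_duration = cfg$segment_duration,
    band_power_map = bpm, frontal_beta_gain = cfg$frontal_beta_gain,
    noise_sd = cfg$noise_sd, valence_effect_size = cfg$valence_effect_size,
    face_keypoints = cfg$face_keypoints, face_dims = cfg$face_dims,
    seed = cfg$seed
  )
  montage <- montage_32()
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    eeg_mat <- as.matrix(utils::read.csv(
      file.path(dir, "eeg", sprintf("trial_%04d.csv", i)), header = FALSE))
    dimnames(eeg_mat) <- NULL
    faces <- list()
    f <- 1
    repeat {
      p <- file.path(dir, "face", sprintf("trial_%04d_frame_%02d.csv", i, f))
      if (!file.exists(p)) break
      fm <- as.matrix(utils::read.csv(p, header = FALSE))
      dimnames(fm) <- NULL
      faces[[f]] <- fm
      f <- f + 1
    }
    list(eeg = raw_eeg(eeg_mat, config$sampling_rate, montage),
         face = faces,
         label = emotion_label(manifest$arousal[i], manifest$valence[i]))
  })
  structure(list(trials = trials, manifest = manifest, config = config),
            class = "synth_dataset")
}
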