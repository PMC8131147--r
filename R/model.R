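# End-to-end multimodal model: BCN feature extraction on both modalities,
# spatial band attention and attention-gated bidirectional LSTMs per
# stream, sigmoid stream fusion, a third bidirectional LSTM over the fused
# sequence, two classification heads (arousal, valence), and the compound
# AM-Softmax objective with feature-, fused- and decision-level branches.

#' Pipeline run configuration
#'
#' Validated container for every tunable of the end-to-end pipeline.
#' Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A validated `run_config` list.
#' @section Keys:
#' \describe{
#'   \item{segment_T}{EEG segment duration, s (frame-rate alignment).}
#'   \item{resolution}{Topography side length, pixels.}
#'   \item{denoise, denoise_level}{Wavelet soft-threshold denoising switch
#'     and depth.}
#'   \item{grid, support, spatial_bins, n_orientations}{Scalp-map keypoint
#'     grid and descriptor shape (descriptor length is
#'     `spatial_bins^2 * n_orientations`).}
#'   \item{bcn_left, bcn_right, bcn_filters, bcn_filter_len, bcn_pool,
#'     bcn_fc1}{BCN channel counts and fully connected width.}
#'   \item{feat_dim}{Stream feature dimension (BCN output / LSTM input).}
#'   \item{d_h}{LSTM hidden size per direction.}
#'   \item{d_fuse}{Width of the fused representation f_t.}
#'   \item{subspaces}{Subspace count k for feature fusion (must divide
#'     `2 * d_h`).}
#'   \item{loss_s, loss_m}{AM-Softmax scale and margin.}
#'   \item{enable_sf, enable_df}{Toggle the fused-feature and
#'     decision-fusion loss branches.}
#'   \item{streams}{`"both"`, `"eeg"` or `"face"`.}
#'   \item{epochs, batch_size, lr, dropout}{Optimizer settings (Adam).}
#'   \item{max_segments}{Cap on per-trial sequence length.}
#'   \item{seed}{Root seed for initialisation, shuffling and dropout.}
#' }
#' @export
run_config <- function(...) {
  defaults <- list(
    segment_T = 0.5, resolution = 32L, denoise = FALSE, denoise_level = 4L,
    grid = 3L, support = 8L, spatial_bins = 2L, n_orientations = 8L,
    bcn_left = 2L, bcn_right = 2L, bcn_filters = 2L, bcn_filter_len = 3L,
    bcn_pool = 2L, bcn_fc1 = 32L,
    feat_dim = 16L, d_h = 16L, d_fuse = 32L, subspaces = 4L,
    loss_s = 10, loss_m = 0.2, enable_sf = TRUE, enable_df = TRUE,
    streams = "both", epochs = 20L, batch_size = 30L, lr = 5e-3,
    dropout = 0.1, max_segments = 25L, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    abort_config(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$streams %in% c("both", "eeg", "face"))
    abort_config("streams must be 'both', 'eeg' or 'face'")
  if ((2L * cfg$d_h) %% cfg$subspaces != 0)
    abort_config("subspaces must divide 2 * d_h")
  if (cfg$lr <= 0 || cfg$epochs < 1 || cfg$batch_size < 1)
    abort_config("invalid optimizer settings")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    abort_config("dropout must be in [0, 1)")
  structure(cfg, class = "run_config")
}

#' Precompute model inputs from a synthetic dataset
#'
#' Runs the EEG branch preprocessing (optional denoising, segmentation,
#' band powers, topographies, grid-keypoint descriptors) and collects the
#' face feature matrices, truncating both streams to the same number of
#' time steps.
#'
#' @param dataset A `synth_dataset`.
#' @param config A [run_config()].
#' @return List with `eeg` (trials x time x band feature matrices), `face`
#'   (trials x time feature matrices), label vectors and dimension info.
#' @export
prepare_features <- function(dataset, config) {
  bands <- eeg_bands()[c("alpha", "beta", "theta")]
  n_desc <- config$spatial_bins^2 * config$n_orientations
  trials <- dataset$trials
  eeg <- vector("list", length(trials))
  face <- vector("list", length(trials))
  n_steps <- Inf
  for (i in seq_along(trials)) {
    topo <- eeg_topo_sequence(trials[[i]]$eeg, T = config$segment_T,
                              bands = bands, resolution = config$resolution,
                              denoise = config$denoise,
                              denoise_level = config$denoise_level)
    keep <- seq_len(min(length(topo), config$max_segments,
                        length(trials[[i]]$face)))
    eeg[[i]] <- lapply(topo[keep], function(seg) {
      lapply(seg, function(img)
        build_feature_matrix(img$pixels, grid = config$grid,
                             support = config$support,
                             spatial_bins = config$spatial_bins,
                             n_orientations = config$n_orientations))
    })
    face[[i]] <- trials[[i]]$face[keep]
    n_steps <- min(n_steps, length(keep))
  }
  eeg <- lapply(eeg, function(x) x[seq_len(n_steps)])
  face <- lapply(face, function(x) x[seq_len(n_steps)])
  list(
    eeg = eeg, face = face,
    arousal = vapply(trials, function(t) t$label$arousal, 0L),
    valence = vapply(trials, function(t) t$label$valence, 0L),
    n_steps = n_steps,
    eeg_M = config$grid^2, eeg_N = n_desc,
    face_M = nrow(face[[1]][[1]]), face_N = ncol(face[[1]][[1]])
  )
}

model_dims <- function(feats, config) {
  list(
    bcn_eeg = bcn_config(
      M = feats$eeg_M, N = feats$eeg_N, N_out = min(feats$eeg_N, 8L),
      n_left = config$bcn_left, n_right = config$bcn_right,
      filter_len = config$bcn_filter_len, n_filters = config$bcn_filters,
      pool_size = config$bcn_pool,
      fc_dims = c(config$bcn_fc1, config$feat_dim)),
    bcn_face = bcn_config(
      M = feats$face_M, N = feats$face_N, N_out = min(feats$face_N, 8L),
      n_left = config$bcn_left, n_right = config$bcn_right,
      filter_len = config$bcn_filter_len, n_filters = config$bcn_filters,
      pool_size = config$bcn_pool,
      fc_dims = c(config$bcn_fc1, config$feat_dim)),
    n_steps = feats$n_steps
  )
}

init_model_params <- function(config, dims) {
  d <- config$feat_dim
  dh <- config$d_h
  with_seed(config$seed, {
    s <- function() sample.int(1e6, 1L)
    att_dir <- function() list(W = rand_mat(dh, 3L), b = matrix(0, 1L, 3L))
    clf <- function(din) rand_mat(din, 3L)
    list(
      bcn_eeg = bcn_init(dims$bcn_eeg, s()),
      bcn_face = bcn_init(dims$bcn_face, s()),
      eeg_att = list(fwd = att_dir(), bwd = att_dir()),
      eeg_fc = list(w = rand_mat(d, d), b = matrix(0, 1L, d)),
      eeg_l1 = bilstm_init(d, dh, s(), use_gate = TRUE),
      expr_l1 = bilstm_init(d, dh, s(), use_gate = TRUE),
      fuse = list(w = rand_mat(ncol_fuse(config), config$d_fuse),
                  b = matrix(0, 1L, config$d_fuse)),
      l3 = bilstm_init(config$d_fuse, dh, s(), use_gate = TRUE),
      clf = list(expr_ar = clf(2L * dh), expr_va = clf(2L * dh),
                 eeg_ar = clf(2L * dh), eeg_va = clf(2L * dh),
                 fused_ar = clf(2L * dh), fused_va = clf(2L * dh),
                 sf_ar = clf(2L * dh), sf_va = clf(2L * dh),
                 df_ar = clf(3L), df_va = clf(3L)),
      subspace = subspace_init(2L * dh, config$subspaces, s())
    )
  })
}

ncol_fuse <- function(config) {
  if (config$streams == "both") 4L * config$d_h else 2L * config$d_h
}

# Column-stack the per-sample matrices of a batch: M x (B*N).
stack_batch <- function(mats) do.call(cbind, mats)

# Global standardization statistics per modality, computed on the training
# set. One scalar mean/sd per modality (pooled over bands, segments and
# descriptor entries): centering removes the large common component that
# makes cosine losses ill-conditioned, while a shared shift/scale preserves
# every between-band and between-class contrast.
feature_stats <- function(feats, config) {
  out <- list()
  if (config$streams != "face") {
    v <- unlist(feats$eeg, use.names = FALSE)
    out$eeg <- list(mean = mean(v), sd = stats::sd(v) + 1e-12)
  }
  if (config$streams != "eeg") {
    v <- unlist(feats$face, use.names = FALSE)
    out$face <- list(mean = mean(v), sd = stats::sd(v) + 1e-12)
  }
  out
}

# Assemble one batch: EEG feature matrices of all (time, band, sample)
# triples stacked into one BCN input, likewise for faces.
make_batch <- function(feats, idx, config, stats = NULL) {
  B <- length(idx)
  TT <- feats$n_steps
  out <- list(B = B, TT = TT,
              arousal = feats$arousal[idx], valence = feats$valence[idx])
  if (config$streams != "face") {
    mats <- vector("list", TT * 3L * B)
    pos <- 1L
    for (t in seq_len(TT)) for (band in 1:3) for (b in seq_len(B)) {
      mats[[pos]] <- feats$eeg[[idx[b]]][[t]][[band]]
      pos <- pos + 1L
    }
    out$eeg_stack <- stack_batch(mats)
    if (!is.null(stats$eeg))
      out$eeg_stack <- (out$eeg_stack - stats$eeg$mean) / stats$eeg$sd
  }
  if (config$streams != "eeg") {
    mats <- vector("list", TT * B)
    pos <- 1L
    for (t in seq_len(TT)) for (b in seq_len(B)) {
      mats[[pos]] <- feats$face[[idx[b]]][[t]]
      pos <- pos + 1L
    }
    out$face_stack <- stack_batch(mats)
    if (!is.null(stats$face))
      out$face_stack <- (out$face_stack - stats$face$mean) / stats$face$sd
  }
  out
}

# EEG layer 1: recurrent loop with band attention (driven by the previous
# hidden state of the same direction), a shared FC producing x_e, an input
# attention gate, and the LSTM cell.
run_eeg_layer1 <- function(Fbands, wp, B, masks) {
  dh <- ncol(ad_value(wp$eeg_l1$fwd$lstm$W_hi))
  TT <- length(Fbands)
  run_dir <- function(order, att, dirp, msk) {
    h <- ad_const(matrix(0, B, dh))
    cc <- ad_const(matrix(0, B, dh))
    H <- vector("list", TT)
    TH <- vector("list", TT)
    for (i in seq_along(order)) {
      t <- order[i]
      theta <- ad_softmax_rows(ad_addbias(ad_matmul(h, att$W), att$b))
      TH[[t]] <- theta
      fp <- NULL
      for (band in 1:3) {
        term <- ad_rowscale(Fbands[[t]][[band]], ad_slice_cols(theta, band))
        fp <- if (is.null(fp)) term else ad_add(fp, term)
      }
      x <- ad_tanh(ad_addbias(ad_matmul(fp, wp$eeg_fc$w), wp$eeg_fc$b))
      g <- ad_attention_gate(x, h, dirp$gate)
      m <- if (is.null(msk)) NULL else msk[[i]]
      st <- ad_lstm_step(g$gated, h, cc, dirp$lstm, m)
      h <- st$h; cc <- st$c
      H[[t]] <- h
    }
    list(H = H, theta = TH)
  }
  f <- run_dir(seq_len(TT), wp$eeg_att$fwd, wp$eeg_l1$fwd, masks$fwd)
  b <- run_dir(rev(seq_len(TT)), wp$eeg_att$bwd, wp$eeg_l1$bwd, masks$bwd)
  list(
    H = lapply(seq_len(TT), function(t) ad_cbind(list(f$H[[t]], b$H[[t]]))),
    theta_fwd = f$theta, theta_bwd = b$theta
  )
}

draw_masks <- function(TT, B, dh, p) {
  if (p == 0) return(list(fwd = NULL, bwd = NULL))
  mk <- function() lapply(seq_len(TT), function(t)
    ad_const(matrix(dropout_mask(B * dh, p), B, dh)))
  list(fwd = mk(), bwd = mk())
}

# Build the full forward graph for one batch. Returns nodes for the head
# logits, the loss breakdown and the attention series.
model_forward <- function(wp, batch, config, dims, train = FALSE) {
  B <- batch$B
  TT <- batch$TT
  p <- if (train) config$dropout else 0
  dh <- config$d_h
  stages <- list()
  streams <- list()
  theta <- NULL
  if (!is.null(batch$eeg_stack)) {
    feat_all <- ad_bcn_forward(batch$eeg_stack, wp$bcn_eeg, dims$bcn_eeg,
                               TT * 3L * B)
    stages$bcn_eeg <- feat_all
    Fbands <- lapply(seq_len(TT), function(t) lapply(1:3, function(band) {
      off <- ((t - 1L) * 3L + (band - 1L)) * B
      ad_slice_rows(feat_all, (off + 1L):(off + B))
    }))
    l1 <- run_eeg_layer1(Fbands, wp, B, draw_masks(TT, B, dh, p))
    streams$eeg <- l1$H
    theta <- l1
  }
  if (!is.null(batch$face_stack)) {
    feat_all <- ad_bcn_forward(batch$face_stack, wp$bcn_face, dims$bcn_face,
                               TT * B)
    stages$bcn_face <- feat_all
    xs <- lapply(seq_len(TT), function(t)
      ad_slice_rows(feat_all, ((t - 1L) * B + 1L):(t * B)))
    l1 <- ad_bilstm_layer(xs, wp$expr_l1, B, draw_masks(TT, B, dh, p))
    streams$expr <- l1$H
  }
  # layer 2: per-step sigmoid fusion of whatever streams are present
  fused <- lapply(seq_len(TT), function(t) {
    z <- if (!is.null(streams$expr) && !is.null(streams$eeg))
      ad_cbind(list(streams$expr[[t]], streams$eeg[[t]]))
    else (streams$expr %||% streams$eeg)[[t]]
    ad_sigmoid(ad_addbias(ad_matmul(z, wp$fuse$w), wp$fuse$b))
  })
  l3 <- ad_bilstm_layer(fused, wp$l3, B, draw_masks(TT, B, dh, p))
  pooled <- ad_scale(Reduce(ad_add, l3$H), 1 / TT)
  stages$pooled <- pooled
  # pooled per-stream features (supervised by loss_F and fused by loss_SF)
  pool_stream <- function(H) ad_scale(Reduce(ad_add, H), 1 / TT)
  sf <- list()
  if (!is.null(streams$expr)) sf$expr <- pool_stream(streams$expr)
  if (!is.null(streams$eeg)) sf$eeg <- pool_stream(streams$eeg)
  list(stages = stages, stream_feats = sf, theta = theta, fused = fused)
}

# Per-head decision structure: the supervised features (each stream's
# pooled hidden state plus the pooled fusion-network representation) with
# their classifier posteriors, and the fused-feature (subspace) branch.
# The classification layer of the fusion network is the cosine (AM-Softmax)
# classifier on the pooled layer-3 representation; the decision fusion
# averages every branch posterior and prediction uses that average.
head_graph <- function(fw, wp, head, config) {
  s <- config$loss_s
  pick <- function(nm) wp$clf[[paste0(nm, "_", head)]]
  feats <- fw$stream_feats
  feats$fused <- fw$stages$pooled
  voters <- list()
  logits <- NULL
  for (nm in names(feats)) {
    w <- pick(if (nm == "expr") "expr" else if (nm == "eeg") "eeg" else "fused")
    cosl <- ad_scale(ad_matmul(ad_rownorm(feats[[nm]]),
                               ad_t(ad_rownorm(ad_t(w)))), s)
    if (nm == "fused") logits <- cosl
    voters[[nm]] <- ad_softmax_rows(cosl)
  }
  sf <- NULL
  if (isTRUE(config$enable_sf)) {
    sfu <- ad_subspace_fusion(unname(fw$stream_feats), wp$subspace)
    sf <- sfu$SF
    cosl <- ad_matmul(ad_rownorm(sf), ad_t(ad_rownorm(ad_t(pick("sf")))))
    voters$sf <- ad_softmax_rows(ad_scale(cosl, s))
  }
  avg <- ad_scale(Reduce(ad_add, unname(voters)), 1 / length(voters))
  list(feats = feats, voters = voters, posterior = avg, sf = sf,
       logits = logits)
}

# Loss graph for one head (labels 0..2): total = loss_F + loss_SF + loss_DF.
head_loss_graph <- function(fw, wp, labels, head, config) {
  s <- config$loss_s; m <- config$loss_m
  hg <- head_graph(fw, wp, head, config)
  pick <- function(nm) wp$clf[[paste0(nm, "_", head)]]
  loss_F <- NULL
  for (nm in names(hg$feats)) {
    w <- pick(if (nm == "expr") "expr" else if (nm == "eeg") "eeg" else "fused")
    l <- ad_am_softmax(hg$feats[[nm]], labels, w, s = s, m = m)
    loss_F <- if (is.null(loss_F)) l else ad_add(loss_F, l)
  }
  total <- loss_F
  loss_SF <- NULL
  if (!is.null(hg$sf)) {
    loss_SF <- ad_am_softmax(hg$sf, labels, pick("sf"), s = s, m = m)
    total <- ad_add(total, loss_SF)
  }
  loss_DF <- NULL
  if (isTRUE(config$enable_df)) {
    avg <- hg$posterior
    logp <- ad_log(ad_add(avg, ad_const(matrix(1e-12, nrow(ad_value(avg)),
                                               ncol(ad_value(avg))))))
    loss_DF <- ad_am_softmax(logp, labels, pick("df"), s = s, m = m)
    total <- ad_add(total, loss_DF)
  }
  list(total = total, loss_F = loss_F, loss_SF = loss_SF, loss_DF = loss_DF)
}

check_finite_stages <- function(stages) {
  for (nm in names(stages)) {
    if (!all(is.finite(ad_value(stages[[nm]]))))
      abort_input(paste0("non-finite values first appeared at stage '", nm, "'"))
  }
}

# ---- Adam optimizer -----------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the multimodal emotion-recognition model
#'
#' Mini-batch Adam training of every parameter (BCN, attention, LSTMs,
#' fusion, classifiers, subspace mapping) against the compound AM-Softmax
#' objective, summed over the arousal and valence heads. Deterministic for
#' a fixed `config$seed`.
#'
#' @param dataset A `synth_dataset`, or a precomputed feature list from
#'   [prepare_features()].
#' @param config A [run_config()].
#' @param verbose Print per-epoch losses.
#' @return An `emofuse_model`: `params`, `config`, `dims`, and `log` (one
#'   row per epoch: total and per-branch training losses).
#' @export
train_model <- function(dataset, config = run_config(), verbose = FALSE) {
  feats <- if (inherits(dataset, "synth_dataset"))
    prepare_features(dataset, config) else dataset
  dims <- model_dims(feats, config)
  params <- init_model_params(config, dims)
  n <- length(feats$arousal)
  stats <- feature_stats(feats, config)
  vec <- flatten_params(params)
  opt <- adam_init(length(vec))
  log <- NULL
  with_seed(derive_seed(config$seed, 777), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep <- c(total = 0, loss_F = 0, loss_SF = 0, loss_DF = 0)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        batch <- make_batch(feats, idx, config, stats)
        wp <- ad_wrap_params(params)
        fw <- model_forward(wp, batch, config, dims, train = TRUE)
        la <- head_loss_graph(fw, wp, batch$arousal, "ar", config)
        lv <- head_loss_graph(fw, wp, batch$valence, "va", config)
        loss <- ad_add(la$total, lv$total)
        if (!is.finite(ad_value(loss)[1])) {
          check_finite_stages(fw$stages)
          abort_input("non-finite training loss")
        }
        ad_backward(loss)
        grad <- collect_grads(wp)
        opt <- adam_step(opt, grad, config$lr)
        vec <- vec - opt$delta
        params <- unflatten_params(params, vec)
        gv <- function(x, y) {
          (if (is.null(x)) 0 else ad_value(x)[1]) +
            (if (is.null(y)) 0 else ad_value(y)[1])
        }
        w <- length(idx) / n
        ep <- ep + w * c(ad_value(loss)[1], gv(la$loss_F, lv$loss_F),
                         gv(la$loss_SF, lv$loss_SF), gv(la$loss_DF, lv$loss_DF))
      }
      log <- rbind(log, data.frame(epoch = epoch, total = ep[1],
                                   loss_F = ep[2], loss_SF = ep[3],
                                   loss_DF = ep[4]))
      if (verbose)
        message(sprintf("epoch %3d  total %.4f (F %.4f, SF %.4f, DF %.4f)",
                        epoch, ep[1], ep[2], ep[3], ep[4]))
    }
  })
  rownames(log) <- NULL
  structure(list(params = params, config = config, dims = dims, log = log,
                 stats = stats),
            class = "emofuse_model")
}

#' @export
print.emofuse_model <- function(x, ...) {
  cat(sprintf("<emofuse_model> streams = %s, %d epochs trained, final loss %.4f\n",
              x$config$streams, nrow(x$log), x$log$total[nrow(x$log)]))
  invisible(x)
}

#' Predict labels and export attention weights
#'
#' @param object A trained `emofuse_model`.
#' @param dataset A `synth_dataset` or [prepare_features()] output.
#' @param chunk Evaluation batch size (memory control).
#' @param ... Unused.
#' @return List with `arousal`, `valence` (predicted 0-based levels),
#'   `posterior_ar`, `posterior_va`, and `attention` (list per trial of
#'   T x 3 matrices of band-attention weights, forward/backward averaged).
#' @export
predict.emofuse_model <- function(object, dataset, chunk = 50L, ...) {
  config <- object$config
  feats <- if (inherits(dataset, "synth_dataset"))
    prepare_features(dataset, config) else dataset
  n <- length(feats$arousal)
  wp <- ad_wrap_params(object$params)
  pa <- NULL; pv <- NULL; att <- list()
  for (s0 in seq(1L, n, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, n)
    batch <- make_batch(feats, idx, config, object$stats)
    fw <- model_forward(wp, batch, config, object$dims, train = FALSE)
    # decision-fusion posterior: average over all branch voters
    pa <- rbind(pa, ad_value(head_graph(fw, wp, "ar", config)$posterior))
    pv <- rbind(pv, ad_value(head_graph(fw, wp, "va", config)$posterior))
    if (!is.null(fw$theta)) {
      TT <- batch$TT
      for (b in seq_along(idx)) {
        m <- matrix(0, TT, 3L,
                    dimnames = list(NULL, c("alpha", "beta", "theta")))
        for (t in seq_len(TT)) {
          m[t, ] <- (ad_value(fw$theta$theta_fwd[[t]])[b, ] +
                       ad_value(fw$theta$theta_bwd[[t]])[b, ]) / 2
        }
        att[[idx[b]]] <- m
      }
    }
  }
  list(
    arousal = max.col(pa) - 1L,
    valence = max.col(pv) - 1L,
    posterior_ar = pa, posterior_va = pv,
    attention = if (length(att) > 0) att else NULL
  )
}

#' Evaluate a trained model
#'
#' @param model A trained `emofuse_model`.
#' @param dataset A `synth_dataset` or [prepare_features()] output.
#' @param indices Optional subset of trials to evaluate (e.g. a held-out
#'   test split).
#' @return List with per-head [metrics_report()]s (`arousal`, `valence`),
#'   the predictions, and mean band-attention weights (when the EEG stream
#'   is active).
#' @export
evaluate_model <- function(model, dataset, indices = NULL) {
  feats <- if (inherits(dataset, "synth_dataset"))
    prepare_features(dataset, model$config) else dataset
  if (!is.null(indices)) feats <- subset_features(feats, indices)
  if (length(feats$arousal) == 0) abort_input("empty evaluation set")
  pred <- predict(model, feats)
  out <- list(
    arousal = metrics_report(feats$arousal, pred$arousal),
    valence = metrics_report(feats$valence, pred$valence),
    predictions = pred
  )
  if (!is.null(pred$attention)) {
    out$mean_attention <- colMeans(do.call(rbind, pred$attention))
  }
  out
}

#' Subset a prepared feature list by trial index
#' @param feats [prepare_features()] output.
#' @param idx Trial indices to keep.
#' @return The subset feature list.
#' @export
subset_features <- function(feats, idx) {
  feats$eeg <- feats$eeg[idx]
  feats$face <- feats$face[idx]
  feats$arousal <- feats$arousal[idx]
  feats$valence <- feats$valence[idx]
  feats
}

#' Stratified train/test split over the label grid
#'
#' @param dataset A `synth_dataset` (or its manifest).
#' @param test_frac Fraction of each (arousal, valence) cell held out.
#' @param seed Seed for the within-cell draw.
#' @return List with `train` and `test` index vectors.
#' @export
split_dataset <- function(dataset, test_frac = 0.2, seed = 1) {
  manifest <- if (inherits(dataset, "synth_dataset")) dataset$manifest
              else dataset
  cells <- interaction(manifest$arousal, manifest$valence)
  with_seed(seed, {
    test <- unlist(lapply(levels(cells), function(cl) {
      i <- which(cells == cl)
      if (length(i) == 0) return(integer(0))
      sample(i, max(1L, round(test_frac * length(i))))
    }))
  })
  test <- sort(test)
  list(train = setdiff(seq_len(nrow(manifest)), test), test = test)
}

#' Export per-segment band-attention weights for a trial
#'
#' @param model A trained `emofuse_model`.
#' @param dataset Dataset or prepared features.
#' @param trial Trial index.
#' @param path Optional CSV path to write.
#' @return Data frame with `segment_index`, `theta_alpha`, `theta_beta`,
#'   `theta_theta` (each row sums to 1).
#' @export
export_attention <- function(model, dataset, trial = 1L, path = NULL) {
  feats <- if (inherits(dataset, "synth_dataset"))
    prepare_features(dataset, model$config) else dataset
  pred <- predict(model, subset_features(feats, trial))
  if (is.null(pred$attention))
    abort_input("attention export requires the EEG stream")
  m <- pred$attention[[1]]
  df <- data.frame(segment_index = seq_len(nrow(m)),
                   theta_alpha = m[, "alpha"],
                   theta_beta = m[, "beta"],
                   theta_theta = m[, "theta"])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
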