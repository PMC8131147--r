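# Feature fusion: (i) subspace adaptive-weight fusion -- features are
# projected into k learned subspaces, weighted by a Gaussian kernel of
# their distance to a learned center, summed and concatenated back to the
# original dimension; (ii) a three-layer bidirectional LSTM network that
# models each stream in time, merges the two hidden sequences with a
# sigmoid-squashed linear map, and models the fused sequence again.

#' Initialise subspace-fusion parameters
#'
#' @param df Input feature dimension; must be divisible by `k`.
#' @param k Number of subspaces (`dk = df / k` dimensions each).
#' @param seed Integer seed.
#' @param scale Initialisation scale for the mapping matrices and centers.
#' @return List with `SW` (k matrices `df x dk`) and `M` (k center rows
#'   `1 x dk`); both are meant to be trained by backpropagation.
#' @export
subspace_init <- function(df, k, seed = 1, scale = 0.1) {
  if (df %% k != 0) abort_config("df must be divisible by the subspace count k")
  dk <- df %/% k
  with_seed(seed, list(
    SW = lapply(seq_len(k), function(j) rand_mat(df, dk, scale)),
    M = lapply(seq_len(k), function(j) rand_mat(1L, dk, scale))
  ))
}

#' Subspace adaptive-weight feature fusion
#'
#' For features `f_1..f_n` (rows of `features`) and subspaces `j = 1..k`:
#' `sw_ij = exp(-(1/df) * ||f_i SW_j - M_j||^2)`,
#' `Sf_j = sum_i sw_ij (f_i SW_j)`, and the fused feature is
#' `SF = concat(Sf_1, ..., Sf_k)`, which has the same dimension `df` as
#' each input. Every weight lies in (0, 1], reaching 1 exactly when the
#' projected feature coincides with the subspace center.
#'
#' @param features n x df matrix (one feature per row) or list of vectors.
#' @param params Parameters from [subspace_init()].
#' @return List with `SF` (length-df fused feature) and `weights`
#'   (n x k matrix of adaptive weights `sw_ij`).
#' @export
subspace_fusion <- function(features, params) {
  if (is.list(features)) features <- do.call(rbind, features)
  features <- as_mat(features)
  df <- ncol(features)
  k <- length(params$SW)
  if (any(vapply(params$SW, nrow, 0L) != df))
    abort_config("mapping matrices must have df rows")
  if (df %% k != 0) abort_config("df must be divisible by the subspace count k")
  n <- nrow(features)
  sw <- matrix(0, n, k)
  parts <- vector("list", k)
  for (j in seq_len(k)) {
    P <- features %*% params$SW[[j]] # n x dk
    d2 <- rowSums(sweep(P, 2L, as.vector(params$M[[j]]), `-`)^2)
    sw[, j] <- exp(-d2 / df)
    parts[[j]] <- colSums(P * sw[, j])
  }
  list(SF = unlist(parts, use.names = FALSE), weights = sw)
}

#' Sigmoid stream fusion (layer 2 of the fusion network)
#'
#' `f_t = sigmoid(w [h_expr_t, h_eeg_t] + b)` per time step: a linear map
#' of the concatenated per-stream hidden states squashed into (0, 1).
#'
#' @param h_expr,h_eeg T x d matrices (or single vectors) of per-stream
#'   hidden states, time-aligned.
#' @param w Weight matrix `(d_expr + d_eeg) x d_out`.
#' @param b Length-`d_out` offset.
#' @return T x d_out matrix with entries in (0, 1).
#' @export
fuse_streams <- function(h_expr, h_eeg, w, b) {
  h_expr <- as_mat(h_expr); h_eeg <- as_mat(h_eeg)
  if (nrow(h_expr) != nrow(h_eeg))
    abort_input("stream hidden sequences must be time-aligned")
  z <- cbind(h_expr, h_eeg)
  if (nrow(as_mat(w)) != ncol(z)) abort_input("fusion weight shape mismatch")
  sigmoid(sweep(z %*% as_mat(w), 2L, as.vector(b), `+`))
}

#' Initialise one bidirectional LSTM layer
#'
#' @param d_in Input dimension per time step.
#' @param d_h Hidden size per direction (output is `2 * d_h` wide).
#' @param seed Integer seed.
#' @param use_gate Attach an input attention gate to each direction.
#' @param scale Weight scale.
#' @return List with `fwd` and `bwd` direction parameters (each `lstm` and
#'   optionally `gate`).
#' @export
bilstm_init <- function(d_in, d_h, seed = 1, use_gate = FALSE, scale = NULL) {
  mk <- function(s) {
    p <- list(lstm = lstm_init(d_in, d_h, s, scale))
    if (use_gate) p$gate <- gate_init(d_in, d_h, s + 1L, scale)
    p
  }
  list(fwd = mk(seed), bwd = mk(seed + 1000L))
}

run_lstm_dir <- function(X, dirp, p = 0) {
  d_h <- ncol(as_mat(dirp$lstm$W_hi))
  h <- numeric(d_h); cc <- numeric(d_h)
  H <- matrix(0, nrow(X), d_h)
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    if (!is.null(dirp$gate)) x <- attention_gate(x, h, dirp$gate)$gated
    mask <- if (p > 0) dropout_mask(d_h, p) else NULL
    st <- am_lstm_step(x, h, cc, dirp$lstm, mask)
    h <- st$h; cc <- st$c
    H[t, ] <- h
  }
  H
}

#' Bidirectional LSTM layer over a sequence
#'
#' Runs a forward and a backward LSTM pass (each optionally attention-
#' gated) and concatenates the two per-step hidden states. Reversing the
#' input sequence and swapping the direction parameters reverses the output
#' sequence exactly (with the two halves of the concatenation swapped).
#'
#' @param X T x d matrix, one time step per row (must be nonempty).
#' @param params Parameters from [bilstm_init()].
#' @param p Dropout probability.
#' @return T x (2 d_h) hidden sequence.
#' @export
bilstm_layer <- function(X, params, p = 0) {
  X <- as_mat(X)
  if (nrow(X) < 1L) abort_input("sequence must be nonempty")
  Hf <- run_lstm_dir(X, params$fwd, p)
  Hb <- run_lstm_dir(X[rev(seq_len(nrow(X))), , drop = FALSE], params$bwd, p)
  cbind(Hf, Hb[rev(seq_len(nrow(X))), , drop = FALSE])
}

#' Initialise the three-layer bidirectional fusion network
#'
#' @param d_expr,d_eeg Per-step feature dimensions of the expression and
#'   EEG streams.
#' @param d_h Hidden size per LSTM direction.
#' @param d_fuse Width of the fused representation `f_t`.
#' @param n_classes Classes per head (3 arousal, 3 valence levels).
#' @param seed Integer seed.
#' @param use_gate Attention-gate the LSTM inputs (the AM-LSTM variant).
#' @param scale Weight scale.
#' @return Nested parameter list.
#' @export
fusion_init <- function(d_expr, d_eeg, d_h = 16L, d_fuse = 2L * d_h,
                        n_classes = 3L, seed = 1, use_gate = TRUE,
                        scale = 0.1) {
  with_seed(seed, {
    s <- function() sample.int(1e6, 1L)
    list(
      expr_l1 = bilstm_init(d_expr, d_h, s(), use_gate, scale),
      eeg_l1 = bilstm_init(d_eeg, d_h, s(), use_gate, scale),
      fuse_w = rand_mat(4L * d_h, d_fuse, scale),
      fuse_b = matrix(0, 1L, d_fuse),
      l3 = bilstm_init(d_fuse, d_h, s(), use_gate, scale),
      head_arousal_w = rand_mat(2L * d_h, n_classes, scale),
      head_arousal_b = matrix(0, 1L, n_classes),
      head_valence_w = rand_mat(2L * d_h, n_classes, scale),
      head_valence_b = matrix(0, 1L, n_classes)
    )
  })
}

#' Three-layer bidirectional LSTM fusion forward pass
#'
#' Layer 1 models each stream separately with a bidirectional (attention-
#' gated) LSTM; layer 2 merges the two hidden sequences per step with
#' [fuse_streams()]; layer 3 models the fused sequence with another
#' bidirectional LSTM. The layer-3 hidden states are mean-pooled over time
#' and passed to two fully connected heads (arousal and valence logits).
#'
#' @param expr_seq,eeg_seq T x d feature sequences, time-aligned.
#' @param params Parameters from [fusion_init()].
#' @param p Dropout probability (0 for evaluation).
#' @return List with `arousal` and `valence` logits (length `n_classes`
#'   each), the fused sequence `f` (entries in (0, 1)), and `pooled`.
#' @export
fusion_forward <- function(expr_seq, eeg_seq, params, p = 0) {
  expr_seq <- as_mat(expr_seq); eeg_seq <- as_mat(eeg_seq)
  if (nrow(expr_seq) != nrow(eeg_seq))
    abort_input("stream sequences must have equal length")
  h_expr <- bilstm_layer(expr_seq, params$expr_l1, p)
  h_eeg <- bilstm_layer(eeg_seq, params$eeg_l1, p)
  f <- fuse_streams(h_expr, h_eeg, params$fuse_w, params$fuse_b)
  h3 <- bilstm_layer(f, params$l3, p)
  pooled <- colMeans(h3)
  list(
    arousal = as.vector(matrix(pooled, 1L) %*% params$head_arousal_w +
                          params$head_arousal_b),
    valence = as.vector(matrix(pooled, 1L) %*% params$head_valence_w +
                          params$head_valence_b),
    f = f,
    pooled = pooled
  )
}

# ---- batched autodiff forms --------------------------------------------

# xs: list over time of B x d nodes. Returns list(H = list over time of
# B x 2d_h nodes, fwd_H = forward-direction hidden list, gates = list of
# forward-direction gate nodes or NULL).
ad_bilstm_layer <- function(xs, wp, B, masks = NULL) {
  d_h <- ncol(ad_value(wp$fwd$lstm$W_hi))
  run_dir <- function(order, dirp, msk) {
    h <- ad_const(matrix(0, B, d_h))
    cc <- ad_const(matrix(0, B, d_h))
    H <- vector("list", length(order))
    G <- vector("list", length(order))
    for (i in seq_along(order)) {
      x <- xs[[order[i]]]
      if (!is.null(dirp$gate)) {
        g <- ad_attention_gate(x, h, dirp$gate)
        x <- g$gated
        G[[order[i]]] <- g$gate
      }
      m <- if (is.null(msk)) NULL else msk[[i]]
      st <- ad_lstm_step(x, h, cc, dirp$lstm, m)
      h <- st$h; cc <- st$c
      H[[order[i]]] <- h
    }
    list(H = H, gates = G)
  }
  TT <- length(xs)
  f <- run_dir(seq_len(TT), wp$fwd, masks$fwd)
  b <- run_dir(rev(seq_len(TT)), wp$bwd, masks$bwd)
  list(
    H = lapply(seq_len(TT), function(t) ad_cbind(list(f$H[[t]], b$H[[t]]))),
    fwd = f, bwd = b
  )
}

# features: list of n (B x df) nodes; wp: wrapped subspace params.
# Returns list(SF = B x df node, weights = list n of list k of B x 1 nodes)
ad_subspace_fusion <- function(features, wp) {
  df <- ncol(ad_value(features[[1]]))
  k <- length(wp$SW)
  parts <- vector("list", k)
  weights <- lapply(features, function(f) vector("list", k))
  for (j in seq_len(k)) {
    acc <- NULL
    for (i in seq_along(features)) {
      P <- ad_matmul(features[[i]], wp$SW[[j]])
      D <- ad_addbias(P, ad_scale(wp$M[[j]], -1))
      swij <- ad_exp(ad_scale(ad_rowsums(ad_mul(D, D)), -1 / df))
      weights[[i]][[j]] <- swij
      term <- ad_rowscale(P, swij)
      acc <- if (is.null(acc)) term else ad_add(acc, term)
    }
    parts[[j]] <- acc
  }
  list(SF = ad_cbind(parts), weights = weights)
}
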