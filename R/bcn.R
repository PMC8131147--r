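# Bilinear convolution network (BCN): projection layers that multiply the
# M x N input feature matrix by learned matrices on the left (combining
# keypoints) and right (re-projecting and shrinking the descriptor space),
# a multichannel 1-D convolution + max-pool + tanh block, two fully
# connected layers and an optional softmax head.

#' BCN architecture configuration
#'
#' @param M,N Input feature-matrix size (keypoints x descriptor dims).
#' @param M_out Rows after the left projection (default `M`).
#' @param N_out Columns after the right projection (default `min(N, 32)`;
#'   the right projection is where feature-dimension reduction happens).
#' @param n_left,n_right Number of left / right projection output channels.
#' @param in_channels Input channel count (1 for a single feature matrix).
#' @param filter_len 1-D convolution kernel length (along the descriptor
#'   direction of each row).
#' @param n_filters Convolution output channels.
#' @param pool_size Non-overlapping max-pool window over convolution
#'   positions.
#' @param fc_dims Widths of the two fully connected layers; `fc_dims[2]` is
#'   the output feature dimension.
#' @param n_classes Optional class count for the softmax head.
#' @return A `bcn_config` list.
#' @export
bcn_config <- function(M, N, M_out = M, N_out = min(N, 32L),
                       n_left = 4L, n_right = 4L, in_channels = 1L,
                       filter_len = 3L, n_filters = 4L, pool_size = 2L,
                       fc_dims = c(32L, 16L), n_classes = NULL) {
  n_pos <- N_out - filter_len + 1L
  if (n_pos < 1L) abort_config("filter longer than the projected rows")
  if (pool_size < 1L) abort_config("pool_size must be >= 1")
  n_pool <- n_pos %/% pool_size
  if (n_pool < 1L) abort_config("pool window exceeds the convolution response length")
  structure(list(
    M = M, N = N, M_out = M_out, N_out = N_out,
    n_left = n_left, n_right = n_right, in_channels = in_channels,
    filter_len = filter_len, n_filters = n_filters, pool_size = pool_size,
    n_pos = n_pos, n_pool = n_pool,
    flat_dim = M_out * n_pool * n_filters,
    fc_dims = fc_dims, n_classes = n_classes
  ), class = "bcn_config")
}

# Random weight matrix; when scale is NULL, use 1/sqrt(fan) (the dimension
# contracted away by the multiplication) to keep activations well scaled.
rand_mat <- function(nr, nc, scale = NULL, fan = nr) {
  if (is.null(scale)) scale <- 1 / sqrt(fan)
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

#' Initialise BCN parameters
#'
#' All weights are drawn N(0, scale^2); biases start at zero. The
#' convolution weights are stored as a `(in_ch * filter_len) x n_filters`
#' matrix whose rows are ordered channel-major (channel outer, tap inner).
#'
#' @param config A [bcn_config()].
#' @param seed Integer seed.
#' @param scale Weight standard deviation (`NULL` = 1/sqrt(fan-in)).
#' @return Nested parameter list.
#' @export
bcn_init <- function(config, seed = 1, scale = NULL) {
  with_seed(seed, {
    p <- list(
      left = lapply(seq_len(config$n_left), function(t)
        lapply(seq_len(config$in_channels), function(j)
          rand_mat(config$M_out, config$M, scale, fan = config$M))),
      right = lapply(seq_len(config$n_right), function(t)
        lapply(seq_len(config$n_left), function(j)
          rand_mat(config$N, config$N_out, scale, fan = config$N))),
      conv_w = rand_mat(config$n_right * config$filter_len, config$n_filters,
                        scale),
      conv_b = matrix(0, 1L, config$n_filters),
      fc1_w = rand_mat(config$flat_dim, config$fc_dims[1], scale),
      fc1_b = matrix(0, 1L, config$fc_dims[1]),
      fc2_w = rand_mat(config$fc_dims[1], config$fc_dims[2], scale),
      fc2_b = matrix(0, 1L, config$fc_dims[2])
    )
    if (!is.null(config$n_classes)) {
      p$head_w <- rand_mat(config$fc_dims[2], config$n_classes, scale)
      p$head_b <- matrix(0, 1L, config$n_classes)
    }
    p
  })
}

as_channel_list <- function(inputs) {
  if (is.matrix(inputs)) list(inputs) else inputs
}

#' Left multiple projection layer
#'
#' Output channel t is `O_t = sum_j h_{t,j} I_j`: each learned `M' x M`
#' matrix left-multiplies an input channel, recombining keypoint rows.
#'
#' @param inputs A single `M x N` matrix or list of input-channel matrices.
#' @param weights List (length = output channels) of lists (length = input
#'   channels) of `M' x M` matrices.
#' @return List of `M' x N` output-channel matrices.
#' @export
left_project <- function(inputs, weights) {
  inputs <- as_channel_list(inputs)
  lapply(weights, function(ht) {
    if (length(ht) != length(inputs))
      abort_input("projection channel count does not match the input")
    Reduce(`+`, lapply(seq_along(inputs), function(j) {
      if (ncol(ht[[j]]) != nrow(inputs[[j]]))
        abort_input("left projection shape mismatch")
      ht[[j]] %*% inputs[[j]]
    }))
  })
}

#' Right multiple projection layer
#'
#' Output channel t is `O_t = sum_j I_j h_{t,j}`: each learned `N x N'`
#' matrix right-multiplies an input channel, projecting every row into a
#' new (typically lower-dimensional) descriptor space.
#'
#' @param inputs A matrix or list of `M' x N` channel matrices.
#' @param weights List (output channels) of lists (input channels) of
#'   `N x N'` matrices.
#' @return List of `M' x N'` matrices.
#' @export
right_project <- function(inputs, weights) {
  inputs <- as_channel_list(inputs)
  lapply(weights, function(ht) {
    if (length(ht) != length(inputs))
      abort_input("projection channel count does not match the input")
    Reduce(`+`, lapply(seq_along(inputs), function(j) {
      if (nrow(ht[[j]]) != ncol(inputs[[j]]))
        abort_input("right projection shape mismatch")
      inputs[[j]] %*% ht[[j]]
    }))
  })
}

#' 1-D convolution, max-pooling and tanh activation
#'
#' Convolves each row of every input channel along the descriptor
#' direction with a bank of multichannel 1-D filters, max-pools the
#' responses over non-overlapping position windows, and applies
#' `F = tanh(b_c + Q)` elementwise.
#'
#' @param inputs Matrix or list of `M' x N'` channel matrices.
#' @param filters Array `(filter_len, in_channels, n_filters)`.
#' @param bias Numeric vector, one offset per output filter channel.
#' @param pool_size Non-overlapping max-pool window length.
#' @return Array `(n_filters, M', n_pool)` of activations, all strictly
#'   inside (-1, 1).
#' @export
conv1d_pool_activate <- function(inputs, filters, bias, pool_size = 2L) {
  inputs <- as_channel_list(inputs)
  d <- dim(filters)
  L <- d[1]; C <- d[2]; nf <- d[3]
  if (C != length(inputs)) abort_input("filter channel count mismatch")
  np <- ncol(inputs[[1]]) - L + 1L
  if (np < 1L) abort_input("filter longer than the feature rows")
  n_pool <- np %/% pool_size
  if (n_pool < 1L) abort_input("pool window exceeds the convolution response length")
  mr <- nrow(inputs[[1]])
  out <- array(0, c(nf, mr, n_pool))
  resp <- array(0, c(mr, np, nf))
  for (f in seq_len(nf)) {
    for (ch in seq_len(C)) {
      for (l in seq_len(L)) {
        resp[, , f] <- resp[, , f] +
          filters[l, ch, f] * inputs[[ch]][, l:(l + np - 1L), drop = FALSE]
      }
    }
  }
  for (f in seq_len(nf)) {
    for (p in seq_len(n_pool)) {
      win <- ((p - 1L) * pool_size + 1L):(p * pool_size)
      q <- resp[, win, f, drop = FALSE]
      out[f, , p] <- tanh(bias[f] + apply(q, 1L, max))
    }
  }
  out
}

# canonical flatten order shared by the plain and batched paths:
# position-major, then filter, then row.
flatten_activations <- function(Farr) {
  as.vector(aperm(Farr, c(2L, 1L, 3L)))
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' BCN forward pass
#'
#' `left_project` -> `right_project` -> [conv1d_pool_activate()] ->
#' flatten -> FC(tanh) -> FC(linear) feature vector; when the config has a
#' softmax head, class posteriors are returned as well.
#'
#' @param x An `M x N` feature matrix (or list of input channels).
#' @param params Parameters from [bcn_init()].
#' @param config The matching [bcn_config()].
#' @return List with `feature` (length `fc_dims[2]`) and, with a head,
#'   `posterior` (probabilities summing to 1).
#' @export
bcn_forward <- function(x, params, config) {
  o <- left_project(x, params$left)
  o <- right_project(o, params$right)
  filt <- array(0, c(config$filter_len, config$n_right, config$n_filters))
  for (ch in seq_len(config$n_right)) {
    rows <- ((ch - 1L) * config$filter_len + 1L):(ch * config$filter_len)
    filt[, ch, ] <- params$conv_w[rows, , drop = FALSE]
  }
  Farr <- conv1d_pool_activate(o, filt, as.vector(params$conv_b),
                               config$pool_size)
  flat <- matrix(flatten_activations(Farr), 1L)
  h1 <- tanh(flat %*% params$fc1_w + params$fc1_b)
  feat <- h1 %*% params$fc2_w + params$fc2_b
  out <- list(feature = as.vector(feat))
  if (!is.null(params$head_w)) {
    logits <- as.vector(feat %*% params$head_w + params$head_b)
    out$posterior <- softmax_vec(logits)
  }
  out
}

# ---- batched autodiff forward ------------------------------------------

# xstack: M x (B*N) matrix (per-sample matrices side by side). Returns the
# B x fc_dims[2] feature node. `wp` is the ad-wrapped parameter tree.
ad_bcn_forward <- function(xstack, wp, config, B) {
  x <- if (inherits(xstack, "ad_node")) xstack else ad_const(xstack)
  # left projections: M' x (B*N) per output channel
  left_out <- lapply(wp$left, function(ht) ad_matmul(ht[[1]], x))
  # to row-stacked (B*M') x N, then right projections
  left_rs <- lapply(left_out, ad_colstack_to_rowstack, B = B)
  right_out <- lapply(seq_len(config$n_right), function(t) {
    Reduce(ad_add, lapply(seq_len(config$n_left), function(j) {
      ad_matmul(left_rs[[j]], wp$right[[t]][[j]])
    }))
  })
  # conv: position p response = [slice p..p+L-1 of every channel] %*% conv_w
  L <- config$filter_len
  pos_nodes <- lapply(seq_len(config$n_pos), function(p) {
    z <- ad_cbind(lapply(right_out, ad_slice_cols, idx = p:(p + L - 1L)))
    ad_matmul(z, wp$conv_w)
  })
  pooled <- lapply(seq_len(config$n_pool), function(pp) {
    win <- ((pp - 1L) * config$pool_size + 1L):(pp * config$pool_size)
    Reduce(ad_pmax, pos_nodes[win])
  })
  q <- ad_cbind(pooled) # (B*M') x (n_pool * n_filters), position-major blocks
  act <- ad_tanh(ad_addbias(q, ad_tile_cols(wp$conv_b, config$n_pool)))
  flat <- ad_rowstack_to_batchmat(act, B) # B x flat_dim
  h1 <- ad_tanh(ad_addbias(ad_matmul(flat, wp$fc1_w), wp$fc1_b))
  ad_addbias(ad_matmul(h1, wp$fc2_w), wp$fc2_b)
}
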