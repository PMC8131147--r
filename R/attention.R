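# Soft attention components: a softmax attention over the three EEG band
# features (spatial band attention) and a sigmoid attention gate applied to
# the LSTM input at every time step (the AM-LSTM). The softmax couples the
# three band weights (they compete and sum to 1); the temporal gate uses a
# sigmoid precisely so that elements of the input vector are weighted
# independently of one another.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Spatial band attention
#'
#' Computes `theta_i = softmax_i(w_i . h_prev + b_i)` over the three band
#' features and returns the attention-weighted combination
#' `f' = theta_1 f_alpha + theta_2 f_beta + theta_3 f_theta`.
#'
#' @param f_alpha,f_beta,f_theta Same-length numeric feature vectors.
#' @param params List with `W` (3 x d_h matrix of per-band weight rows),
#'   `b` (length-3 bias) and `h_prev` (length-d_h previous hidden state of
#'   the EEG-stream recurrence).
#' @return List with `fused` (the weighted feature) and `weights` (the
#'   three positive attention weights, summing to 1, named alpha/beta/
#'   theta).
#' @export
band_attention <- function(f_alpha, f_beta, f_theta, params) {
  d <- length(f_alpha)
  if (length(f_beta) != d || length(f_theta) != d)
    abort_input("band features must share one dimension")
  h <- as.vector(params$h_prev)
  if (ncol(as_mat(params$W)) != length(h))
    abort_input("attention weight matrix does not match h_prev")
  logits <- as.vector(as_mat(params$W) %*% h) + as.vector(params$b)
  w <- softmax_vec(logits)
  fused <- w[1] * f_alpha + w[2] * f_beta + w[3] * f_theta
  list(fused = fused, weights = stats::setNames(w, c("alpha", "beta", "theta")))
}

#' Temporal attention gate
#'
#' `a_t = sigmoid(W_x x_t + W_h h_prev + b)`, each component in (0, 1),
#' applied elementwise: the gated input is `a_t * x_t`. Unlike a softmax,
#' the sigmoid normalizes every component independently, so equally
#' important elements do not compete.
#'
#' @param x_t Input vector at time t.
#' @param h_prev Previous hidden state.
#' @param params List with `W_x` (d x d), `W_h` (d_h x d), `b` (length d).
#'   Weights use the row-vector convention: the gate computes
#'   `sigmoid(x W_x + h W_h + b)`.
#' @return List with `gated` (`a_t * x_t`) and `gate` (`a_t`).
#' @export
attention_gate <- function(x_t, h_prev, params) {
  if (nrow(as_mat(params$W_x)) != length(x_t) ||
      nrow(as_mat(params$W_h)) != length(h_prev))
    abort_input("attention gate shape mismatch")
  a <- sigmoid(as.vector(matrix(x_t, 1L) %*% as_mat(params$W_x)) +
                 as.vector(matrix(h_prev, 1L) %*% as_mat(params$W_h)) +
                 as.vector(params$b))
  list(gated = a * x_t, gate = a)
}

#' One attention-gated LSTM step
#'
#' Standard LSTM gate equations applied to the (already gated) input, with
#' an inverted-dropout mask applied to the emitted hidden state:
#' `h_t = (o_t * tanh(c_t)) * f_p`. At evaluation `f_p` is all ones; during
#' training its entries are `0` or `1/(1-p)` so no rescaling is needed at
#' test time.
#'
#' @param x_t (Gated) input vector.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @param params List of gate parameters `W_xi, W_hi, b_i, W_xf, W_hf, b_f,
#'   W_xo, W_ho, b_o, W_xc, W_hc, b_c`. Weights use the row-vector
#'   convention (`d x d_h` input matrices, `d_h x d_h` recurrent matrices):
#'   each gate computes `x W_x. + h W_h. + b`.
#' @param mask Dropout mask `f_p` (defaults to all ones).
#' @return List with `h`, `c` and the `gates` (`i`, `f`, `o`), all gate
#'   entries strictly in (0, 1).
#' @export
am_lstm_step <- function(x_t, h_prev, c_prev, params, mask = NULL) {
  lin <- function(Wx, Wh, b) {
    as.vector(matrix(x_t, 1L) %*% as_mat(Wx)) +
      as.vector(matrix(h_prev, 1L) %*% as_mat(Wh)) + as.vector(b)
  }
  if (nrow(as_mat(params$W_xi)) != length(x_t))
    abort_input("LSTM input shape mismatch")
  i <- sigmoid(lin(params$W_xi, params$W_hi, params$b_i))
  f <- sigmoid(lin(params$W_xf, params$W_hf, params$b_f))
  o <- sigmoid(lin(params$W_xo, params$W_ho, params$b_o))
  g <- tanh(lin(params$W_xc, params$W_hc, params$b_c))
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  if (!is.null(mask)) h_t <- h_t * mask
  list(h = h_t, c = c_t, gates = list(i = i, f = f, o = o))
}

#' Inverted-dropout mask
#'
#' Bernoulli(1 - p) keep mask scaled by `1/(1-p)`, so the expected value of
#' the masked vector equals the unmasked one and evaluation needs no
#' rescaling.
#'
#' @param n Mask length.
#' @param p Drop probability in `[0, 1)`.
#' @return Numeric vector with entries in `{0, 1/(1-p)}`.
#' @export
dropout_mask <- function(n, p) {
  if (!is_scalar_number(p) || p < 0 || p >= 1)
    abort_config("dropout probability must be in [0, 1)")
  if (p == 0) return(rep(1, n))
  keep <- stats::rbinom(n, 1L, 1 - p)
  keep / (1 - p)
}

#' Run an attention-gated LSTM over a sequence
#'
#' Applies [attention_gate()] then [am_lstm_step()] at every time step.
#'
#' @param X T x d matrix, one row per time step.
#' @param params List with `gate` ([attention_gate()] parameters) and
#'   `lstm` ([am_lstm_step()] parameters).
#' @param p Dropout probability (0 disables; masks are drawn from the
#'   current RNG state).
#' @return List with `H` (T x d_h hidden sequence), final `h`, `c`, and
#'   `gates` (T x d matrix of attention gate activations).
#' @export
am_lstm_forward <- function(X, params, p = 0) {
  X <- as_mat(X)
  d_h <- nrow(as_mat(params$lstm$W_hi))
  h <- numeric(d_h); cc <- numeric(d_h)
  H <- matrix(0, nrow(X), d_h)
  A <- matrix(0, nrow(X), ncol(X))
  for (t in seq_len(nrow(X))) {
    g <- attention_gate(X[t, ], h, params$gate)
    mask <- if (p > 0) dropout_mask(d_h, p) else NULL
    st <- am_lstm_step(g$gated, h, cc, params$lstm, mask)
    h <- st$h; cc <- st$c
    H[t, ] <- h
    A[t, ] <- g$gate
  }
  list(H = H, h = h, c = cc, gates = A)
}

# ---- parameter initialisers --------------------------------------------

# Gate/LSTM parameters in batched (row-vector) convention: weights are
# stored as d_in x d_out so a batch matrix (B x d_in) right-multiplies them.
lstm_init <- function(d_in, d_h, seed = 1, scale = NULL) {
  with_seed(seed, list(
    W_xi = rand_mat(d_in, d_h, scale), W_hi = rand_mat(d_h, d_h, scale),
    b_i = matrix(0, 1L, d_h),
    W_xf = rand_mat(d_in, d_h, scale), W_hf = rand_mat(d_h, d_h, scale),
    b_f = matrix(1, 1L, d_h), # forget bias 1: remember by default
    W_xo = rand_mat(d_in, d_h, scale), W_ho = rand_mat(d_h, d_h, scale),
    b_o = matrix(0, 1L, d_h),
    W_xc = rand_mat(d_in, d_h, scale), W_hc = rand_mat(d_h, d_h, scale),
    b_c = matrix(0, 1L, d_h)
  ))
}

gate_init <- function(d_in, d_h, seed = 1, scale = NULL) {
  with_seed(seed, list(
    W_x = rand_mat(d_in, d_in, scale),
    W_h = rand_mat(d_h, d_in, scale),
    b = matrix(0, 1L, d_in)
  ))
}

# ---- batched autodiff forms --------------------------------------------

# x: B x d node; h: B x d_h node. wp: wrapped gate params (W_x d x d,
# W_h d_h x d, b 1 x d -- same row-vector convention as attention_gate()).
ad_attention_gate <- function(x, h, wp) {
  a <- ad_sigmoid(ad_addbias(
    ad_add(ad_matmul(x, wp$W_x), ad_matmul(h, wp$W_h)), wp$b))
  list(gated = ad_mul(a, x), gate = a)
}

# One batched LSTM step. x: B x d; h, cc: B x d_h; mask: NULL or B x d_h
# constant matrix of inverted-dropout factors.
ad_lstm_step <- function(x, h, cc, wp, mask = NULL) {
  lin <- function(Wx, Wh, b)
    ad_addbias(ad_add(ad_matmul(x, Wx), ad_matmul(h, Wh)), b)
  i <- ad_sigmoid(lin(wp$W_xi, wp$W_hi, wp$b_i))
  f <- ad_sigmoid(lin(wp$W_xf, wp$W_hf, wp$b_f))
  o <- ad_sigmoid(lin(wp$W_xo, wp$W_ho, wp$b_o))
  g <- ad_tanh(lin(wp$W_xc, wp$W_hc, wp$b_c))
  c_t <- ad_add(ad_mul(f, cc), ad_mul(i, g))
  h_t <- ad_mul(o, ad_tanh(c_t))
  if (!is.null(mask)) h_t <- ad_mul(h_t, mask)
  list(h = h_t, c = c_t)
}
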