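# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own vectorised code paths: plain loops and direct
# formula transcriptions only.

oracle_softmax <- function(z) {
  e <- exp(z)
  e / sum(e)
}

# naive Welch-free band energy: direct DFT sums (Parseval form)
oracle_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  p <- Mod(X)^2 / n^2
  # one-sided fold
  keep <- freqs >= lo & freqs < hi
  keep2 <- (fs - freqs) >= lo & (fs - freqs) < hi & freqs > fs / 2
  sum(p[keep]) + sum(p[keep2])
}

oracle_total_energy <- function(x) mean(x^2)

# triple-loop left projection: O_t = sum_j h_tj %*% I_j
oracle_left_project <- function(inputs, weights) {
  lapply(weights, function(ht) {
    acc <- NULL
    for (j in seq_along(inputs)) {
      o <- matrix(0, nrow(ht[[j]]), ncol(inputs[[j]]))
      for (r in seq_len(nrow(o))) for (cc in seq_len(ncol(o)))
        for (k in seq_len(ncol(ht[[j]])))
          o[r, cc] <- o[r, cc] + ht[[j]][r, k] * inputs[[j]][k, cc]
      acc <- if (is.null(acc)) o else acc + o
    }
    acc
  })
}

oracle_right_project <- function(inputs, weights) {
  lapply(weights, function(ht) {
    acc <- NULL
    for (j in seq_along(inputs)) {
      o <- matrix(0, nrow(inputs[[j]]), ncol(ht[[j]]))
      for (r in seq_len(nrow(o))) for (cc in seq_len(ncol(o)))
        for (k in seq_len(nrow(ht[[j]])))
          o[r, cc] <- o[r, cc] + inputs[[j]][r, k] * ht[[j]][k, cc]
      acc <- if (is.null(acc)) o else acc + o
    }
    acc
  })
}

# naive conv + pool + tanh, elementwise loops
oracle_conv_block <- function(inputs, filters, bias, pool) {
  d <- dim(filters)
  L <- d[1]; C <- d[2]; nf <- d[3]
  mr <- nrow(inputs[[1]]); np <- ncol(inputs[[1]]) - L + 1
  n_pool <- np %/% pool
  out <- array(0, c(nf, mr, n_pool))
  for (f in seq_len(nf)) for (i in seq_len(mr)) for (pp in seq_len(n_pool)) {
    best <- -Inf
    for (p in ((pp - 1) * pool + 1):(pp * pool)) {
      q <- 0
      for (ch in seq_len(C)) for (l in seq_len(L))
        q <- q + filters[l, ch, f] * inputs[[ch]][i, p + l - 1]
      if (q > best) best <- q
    }
    out[f, i, pp] <- tanh(bias[f] + best)
  }
  out
}

# scalar-by-scalar LSTM step
oracle_lstm_step <- function(x, h, cc, p, mask = NULL) {
  sig <- function(z) 1 / (1 + exp(-z))
  d_h <- ncol(p$W_hi)
  lin <- function(Wx, Wh, b) {
    out <- numeric(d_h)
    for (k in seq_len(d_h)) {
      s <- b[k]
      for (j in seq_along(x)) s <- s + x[j] * Wx[j, k]
      for (j in seq_along(h)) s <- s + h[j] * Wh[j, k]
      out[k] <- s
    }
    out
  }
  i <- sig(lin(p$W_xi, p$W_hi, p$b_i))
  f <- sig(lin(p$W_xf, p$W_hf, p$b_f))
  o <- sig(lin(p$W_xo, p$W_ho, p$b_o))
  g <- tanh(lin(p$W_xc, p$W_hc, p$b_c))
  c_t <- f * cc + i * g
  h_t <- o * tanh(c_t)
  if (!is.null(mask)) h_t <- h_t * mask
  list(h = h_t, c = c_t)
}

# double-loop subspace fusion (Eq. 6 transcription)
oracle_subspace_fusion <- function(F, SW, M) {
  n <- nrow(F); df <- ncol(F); k <- length(SW)
  dk <- ncol(SW[[1]])
  SF <- c()
  sw <- matrix(0, n, k)
  for (j in seq_len(k)) {
    Sfj <- numeric(dk)
    for (i in seq_len(n)) {
      proj <- as.vector(F[i, , drop = FALSE] %*% SW[[j]])
      d2 <- sum((proj - as.vector(M[[j]]))^2)
      sw[i, j] <- exp(-d2 / df)
      Sfj <- Sfj + sw[i, j] * proj
    }
    SF <- c(SF, Sfj)
  }
  list(SF = SF, weights = sw)
}

# direct log-sum-exp cross entropy from explicit logits
oracle_ce <- function(logits, labels) {
  n <- nrow(logits)
  tot <- 0
  for (i in seq_len(n)) {
    z <- logits[i, ]
    tot <- tot - log(exp(z[labels[i] + 1]) / sum(exp(z)))
  }
  tot / n
}

oracle_cosine <- function(x, w) {
  out <- matrix(0, nrow(x), ncol(w))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(w))) {
    out[i, j] <- sum(x[i, ] * w[, j]) /
      (sqrt(sum(x[i, ]^2)) * sqrt(sum(w[, j]^2)))
  }
  out
}

rand_params_lstm <- function(d_in, d_h, seed = 1) {
  set.seed(seed)
  rm <- function(a, b) matrix(rnorm(a * b, sd = 0.4), a, b)
  list(W_xi = rm(d_in, d_h), W_hi = rm(d_h, d_h), b_i = matrix(rnorm(d_h), 1),
       W_xf = rm(d_in, d_h), W_hf = rm(d_h, d_h), b_f = matrix(rnorm(d_h), 1),
       W_xo = rm(d_in, d_h), W_ho = rm(d_h, d_h), b_o = matrix(rnorm(d_h), 1),
       W_xc = rm(d_in, d_h), W_hc = rm(d_h, d_h), b_c = matrix(rnorm(d_h), 1))
}
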