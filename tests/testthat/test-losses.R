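# Cross-entropy, cosine softmax, AM-Softmax, and the compound objective.

test_that("cross entropy: uniform logits give ln 3, saturated logits vanish, oracle", {
  X <- matrix(0, 4, 5)
  W <- matrix(0, 5, 3)
  expect_equal(cross_entropy_loss(X, c(0, 1, 2, 0), W), log(3), tolerance = 1e-12)

  W2 <- matrix(0, 2, 3); W2[, 2] <- 20
  X2 <- matrix(1, 3, 2)
  expect_lt(cross_entropy_loss(X2, c(1, 1, 1), W2), 1e-8)

  set.seed(1)
  X3 <- matrix(rnorm(12), 4, 3); W3 <- matrix(rnorm(9), 3, 3); b3 <- rnorm(3)
  labs <- c(0, 2, 1, 0)
  want <- oracle_ce(X3 %*% W3 + rep(b3, each = 4), labs)
  expect_lt(abs(cross_entropy_loss(X3, labs, W3, b3) - want), 1e-10)
  expect_error(cross_entropy_loss(X3, c(0, 1, 5, 0), W3),
               class = "emofuse_input_error")
})

test_that("cosine softmax: worked two-class case, scale invariance, oracle", {
  # x aligned with its class weight and orthogonal to the other:
  # logits are cos = 1 and 0, so L = -log(e / (e + 1))
  x <- matrix(c(1, 0), 1, 2)
  W <- cbind(c(1, 0), c(0, 1))
  expect_equal(cosine_softmax_loss(x, 0, W), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_lt(abs(cosine_softmax_loss(x, 0, W) - 0.3133), 1e-4)
  expect_lt(abs(cosine_softmax_loss(1000 * x, 0, W) -
                  cosine_softmax_loss(x, 0, W)), 1e-12)

  set.seed(2)
  X <- matrix(rnorm(12), 4, 3); W3 <- matrix(rnorm(9), 3, 3)
  labs <- c(2, 1, 0, 2)
  want <- oracle_ce(oracle_cosine(X, W3), labs)
  expect_lt(abs(cosine_softmax_loss(X, labs, W3) - want), 1e-10)
  expect_error(cosine_softmax_loss(matrix(0, 1, 3), 0, W3),
               class = "emofuse_input_error")
})

test_that("AM-Softmax: reduces to cosine softmax at (s=1, m=0), monotone in m, oracle", {
  set.seed(3)
  X <- matrix(rnorm(15), 5, 3); W <- matrix(rnorm(9), 3, 3)
  labs <- c(0, 1, 2, 1, 0)
  expect_lt(abs(am_softmax_loss(X, labs, W, s = 1, m = 0) -
                  cosine_softmax_loss(X, labs, W)), 1e-12)
  expect_gt(am_softmax_loss(X, labs, W, s = 4, m = 0.35),
            am_softmax_loss(X, labs, W, s = 4, m = 0))

  s <- 7; m <- 0.25
  cosm <- oracle_cosine(X, W)
  adj <- cosm
  for (i in seq_along(labs)) adj[i, labs[i] + 1] <- adj[i, labs[i] + 1] - m
  want <- oracle_ce(s * adj, labs)
  expect_lt(abs(am_softmax_loss(X, labs, W, s = s, m = m) - want), 1e-10)

  expect_error(am_softmax_loss(X, labs, W, s = -1), class = "emofuse_config_error")
  expect_error(am_softmax_loss(X, labs, W, m = 1.2), class = "emofuse_config_error")
})

test_that("AM-Softmax gradients match finite differences", {
  set.seed(4)
  X <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(9), 3, 3)
  labs <- c(0, 1, 2, 1)
  p <- list(X = X, W = W)
  build <- function(pp) {
    wp <- emofuse:::ad_wrap_params(pp)
    list(loss = emofuse:::ad_am_softmax(wp$X, labs, wp$W, s = 4, m = 0.3),
         wp = wp)
  }
  res <- build(p)
  ad_backward(res$loss)
  g <- emofuse:::collect_grads(res$wp)
  fd <- emofuse:::numeric_grad(function(pp) ad_value(build(pp)$loss)[1], p,
                               eps = 1e-6)
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-4)
})

test_that("compound loss: degenerate sum, duplication additivity, summed oracle", {
  set.seed(5)
  f1 <- matrix(rnorm(12), 4, 3)
  W1 <- matrix(rnorm(9), 3, 3)
  labs <- c(0, 1, 2, 0)
  single <- total_loss(list(f1), labs, list(W1))
  expect_equal(single$total, single$loss_F)
  expect_equal(single$loss_SF, 0)
  expect_equal(single$loss_DF, 0)

  dup <- total_loss(list(f1, f1), labs, list(W1, W1))
  expect_equal(dup$loss_F, 2 * single$loss_F, tolerance = 1e-12)

  f2 <- matrix(rnorm(12), 4, 3); f3 <- matrix(rnorm(12), 4, 3)
  W2 <- matrix(rnorm(9), 3, 3); W3 <- matrix(rnorm(9), 3, 3)
  sfW <- matrix(rnorm(9), 3, 3); dfW <- matrix(rnorm(9), 3, 3)
  post <- matrix(runif(12), 4, 3); post <- post / rowSums(post)
  out <- total_loss(list(f1, f2, f3), labs, list(W1, W2, W3),
                    sf_feature = f2, sf_classifier = sfW,
                    df_posterior = post, df_classifier = dfW, s = 6, m = 0.2)
  want_F <- am_softmax_loss(f1, labs, W1, 6, 0.2) +
    am_softmax_loss(f2, labs, W2, 6, 0.2) +
    am_softmax_loss(f3, labs, W3, 6, 0.2)
  expect_lt(abs(out$loss_F - want_F), 1e-10)
  expect_equal(out$total, out$loss_F + out$loss_SF + out$loss_DF)
  expect_true(all(c(out$loss_F, out$loss_SF, out$loss_DF) >= 0))
  expect_error(total_loss(list(f1, f2), labs, list(W1)),
               class = "emofuse_input_error")
})

test_that("the additive margin widens the angles between learned class means", {
  # train a small feature matrix + classifier under the AM-Softmax with and
  # without margin; the margin run should end with a larger minimum
  # inter-class angle between class-mean features (majority over 3 seeds)
  run <- function(seed, m) {
    set.seed(seed)
    n <- 30; d <- 4
    labs <- rep(0:2, each = n / 3)
    p <- list(X = matrix(rnorm(n * d), n, d), W = matrix(rnorm(d * 3), d, 3))
    vec <- emofuse:::flatten_params(p)
    opt <- emofuse:::adam_init(length(vec))
    for (it in 1:250) {
      pp <- emofuse:::unflatten_params(p, vec)
      wp <- emofuse:::ad_wrap_params(pp)
      loss <- emofuse:::ad_am_softmax(wp$X, labs, wp$W, s = 30, m = m)
      ad_backward(loss)
      opt <- emofuse:::adam_step(opt, emofuse:::collect_grads(wp), 1e-2)
      vec <- vec - opt$delta
    }
    X <- emofuse:::unflatten_params(p, vec)$X
    cm <- t(vapply(0:2, function(k) colMeans(X[labs == k, , drop = FALSE]),
                   numeric(d)))
    cmn <- cm / sqrt(rowSums(cm^2))
    cs <- cmn %*% t(cmn)
    min(acos(pmin(pmax(cs[upper.tri(cs)], -1), 1)))
  }
  wins <- sum(vapply(1:3, function(sd) run(sd, 0.35) > run(sd, 0), logical(1)))
  expect_gte(wins, 2)
})
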