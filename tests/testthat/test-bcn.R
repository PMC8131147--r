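# Bilinear convolution network: projections, conv block, descriptors,
# forward pass and trainability.

test_that("left projection: identities, channel sums, and loop oracle", {
  set.seed(1)
  X <- matrix(rnorm(20), 4, 5)
  id <- diag(4)
  expect_equal(left_project(X, list(list(id)))[[1]], X)
  expect_equal(left_project(list(X, X), list(list(id, id)))[[1]], 2 * X)

  inputs <- lapply(1:3, function(i) matrix(rnorm(20), 4, 5))
  weights <- lapply(1:2, function(t) lapply(1:3, function(j) matrix(rnorm(12), 3, 4)))
  got <- left_project(inputs, weights)
  want <- oracle_left_project(inputs, weights)
  for (t in 1:2) expect_lt(max(abs(got[[t]] - want[[t]])), 1e-10)
  expect_error(left_project(X, list(list(matrix(0, 3, 5)))),
               class = "emofuse_input_error")
})

test_that("right projection: identity, row sums, dimension reduction, oracle", {
  set.seed(2)
  X <- matrix(rnorm(20), 4, 5)
  expect_equal(right_project(X, list(list(diag(5))))[[1]], X)
  ones <- matrix(1, 5, 1)
  expect_equal(as.vector(right_project(X, list(list(ones)))[[1]]), rowSums(X))

  inputs <- lapply(1:2, function(i) matrix(rnorm(20), 4, 5))
  weights <- lapply(1:3, function(t) lapply(1:2, function(j) matrix(rnorm(15), 5, 3)))
  got <- right_project(inputs, weights)
  want <- oracle_right_project(inputs, weights)
  for (t in 1:3) expect_lt(max(abs(got[[t]] - want[[t]])), 1e-10)
})

test_that("projection layers are linear operators", {
  set.seed(3)
  weights <- lapply(1:2, function(t) lapply(1:1, function(j) matrix(rnorm(16), 4, 4)))
  A <- matrix(rnorm(24), 4, 6); B <- matrix(rnorm(24), 4, 6)
  lp <- function(x) left_project(x, weights)
  for (t in 1:2) {
    expect_lt(max(abs(lp(A + B)[[t]] - (lp(A)[[t]] + lp(B)[[t]]))), 1e-10)
    expect_lt(max(abs(lp(2.5 * A)[[t]] - 2.5 * lp(A)[[t]])), 1e-10)
  }
})

test_that("conv block: zero case, tanh bound, naive oracle", {
  set.seed(4)
  inputs <- lapply(1:2, function(i) matrix(rnorm(28), 4, 7))
  filters <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  bias <- rnorm(3)
  got <- conv1d_pool_activate(inputs, filters, bias, pool_size = 2)
  want <- oracle_conv_block(inputs, filters, bias, 2)
  expect_lt(max(abs(got - want)), 1e-10)
  expect_true(all(abs(got) < 1))

  z <- conv1d_pool_activate(lapply(1:2, function(i) matrix(0, 4, 7)),
                            array(0, c(2, 2, 3)), rep(0, 3), 2)
  expect_true(all(z == 0))
  expect_error(conv1d_pool_activate(inputs, filters, bias, pool_size = 20),
               class = "emofuse_input_error")
})

test_that("bcn forward: posteriors normalize, zero propagates, plain equals batched path", {
  cfgb <- bcn_config(M = 5, N = 12, N_out = 6, n_left = 2, n_right = 2,
                     filter_len = 3, n_filters = 2, pool_size = 2,
                     fc_dims = c(8, 4), n_classes = 3)
  p <- bcn_init(cfgb, seed = 6)
  set.seed(7)
  X <- matrix(rnorm(60), 5, 12)
  out <- bcn_forward(X, p, cfgb)
  expect_equal(sum(out$posterior), 1, tolerance = 1e-8)

  p0 <- p
  p0$fc1_b[] <- 0; p0$fc2_b[] <- 0; p0$conv_b[] <- 0
  out0 <- bcn_forward(matrix(0, 5, 12), p0, cfgb)
  expect_true(all(abs(out0$feature) < 1e-12))

  # the batched autodiff path agrees with the plain path
  X2 <- matrix(rnorm(60), 5, 12)
  wp <- emofuse:::ad_wrap_params(p[setdiff(names(p), c("head_w", "head_b"))])
  node <- emofuse:::ad_bcn_forward(cbind(X, X2), wp, cfgb, 2L)
  batched <- ad_value(node)
  expect_equal(batched[1, ], bcn_forward(X, p, cfgb)$feature, tolerance = 1e-10)
  expect_equal(batched[2, ], bcn_forward(X2, p, cfgb)$feature, tolerance = 1e-10)
})

test_that("bcn gradients match finite differences on a 4x6 input", {
  cfgb <- bcn_config(M = 4, N = 6, N_out = 5, n_left = 2, n_right = 2,
                     filter_len = 2, n_filters = 2, pool_size = 2,
                     fc_dims = c(5, 3))
  p <- bcn_init(cfgb, seed = 8)
  set.seed(9)
  X <- matrix(rnorm(24), 4, 6)
  tgt <- matrix(rnorm(6), 2, 3)
  lossf <- function(pp) {
    wp <- emofuse:::ad_wrap_params(pp)
    f <- emofuse:::ad_bcn_forward(cbind(X, 0.5 * X), wp, cfgb, 2L)
    d <- emofuse:::ad_sub(f, emofuse:::ad_const(tgt))
    ad_value(emofuse:::ad_sum(emofuse:::ad_mul(d, d)))[1]
  }
  wp <- emofuse:::ad_wrap_params(p)
  f <- emofuse:::ad_bcn_forward(cbind(X, 0.5 * X), wp, cfgb, 2L)
  d <- emofuse:::ad_sub(f, emofuse:::ad_const(tgt))
  ad_backward(emofuse:::ad_sum(emofuse:::ad_mul(d, d)))
  g <- emofuse:::collect_grads(wp)
  fd <- emofuse:::numeric_grad(lossf, p, eps = 1e-5)
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-4)
})

test_that("descriptors: constant image is zero, output deterministic, rotation permutes bins", {
  img <- matrix(5, 20, 20)
  fm <- build_feature_matrix(img, grid = 2, support = 8, spatial_bins = 2)
  expect_true(all(fm == 0))

  set.seed(11)
  img2 <- matrix(runif(400), 20, 20)
  expect_identical(build_feature_matrix(img2, grid = 2),
                   build_feature_matrix(img2, grid = 2))

  # oriented grating at 22.5 degrees; rotating the patch by 90 degrees
  # shifts the orientation histogram by exactly 2 of 8 bins
  n <- 12
  ang <- 22.5 * pi / 180
  gr <- outer(seq_len(n), seq_len(n), function(r, cc)
    sin(0.9 * (cos(ang) * cc + sin(ang) * r)))
  rot <- t(gr[nrow(gr):1, ]) # 90-degree rotation
  kp <- c(n / 2, n / 2)
  d0 <- sift_descriptor(gr, kp, support = 8, spatial_bins = 1, n_orientations = 8)
  d90 <- sift_descriptor(rot, kp, support = 8, spatial_bins = 1, n_orientations = 8)
  perm <- ((seq_len(8) - 1 + 2) %% 8) + 1 # +90 degrees = +2 bins
  expect_equal(d90[perm], d0, tolerance = 0.05 * max(d0))

  expect_error(sift_descriptor(img2, c(1, 1), support = 8),
               class = "emofuse_input_error")
})

test_that("a BCN with a margin classifier trains on separable feature matrices", {
  cfgb <- bcn_config(M = 4, N = 8, N_out = 6, n_left = 2, n_right = 2,
                     filter_len = 3, n_filters = 2, pool_size = 2,
                     fc_dims = c(8, 4))
  p <- bcn_init(cfgb, seed = 13)
  p$clf <- emofuse:::rand_mat(4, 2)
  set.seed(14)
  n <- 24
  labs <- rep(0:1, n / 2)
  base <- list(matrix(rnorm(32), 4, 8), matrix(rnorm(32), 4, 8))
  mats <- lapply(seq_len(n), function(i) base[[labs[i] + 1]] +
                   matrix(rnorm(32, sd = 0.3), 4, 8))
  xstack <- do.call(cbind, mats)
  lossf <- function(pp) {
    wp <- emofuse:::ad_wrap_params(pp)
    f <- emofuse:::ad_bcn_forward(xstack, wp[names(pp) != "clf"], cfgb, n)
    emofuse:::ad_am_softmax(f, labs, wp$clf, s = 10, m = 0.2)
  }
  vec <- emofuse:::flatten_params(p)
  opt <- emofuse:::adam_init(length(vec))
  l0 <- NULL
  for (it in 1:200) {
    pp <- emofuse:::unflatten_params(p, vec)
    wp <- emofuse:::ad_wrap_params(pp)
    f <- emofuse:::ad_bcn_forward(xstack, wp[names(pp) != "clf"], cfgb, n)
    loss <- emofuse:::ad_am_softmax(f, labs, wp$clf, s = 10, m = 0.2)
    if (it == 1) l0 <- ad_value(loss)[1]
    ad_backward(loss)
    opt <- emofuse:::adam_step(opt, emofuse:::collect_grads(wp), 5e-3)
    vec <- vec - opt$delta
  }
  expect_lt(ad_value(loss)[1], 0.5 * l0)
})
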