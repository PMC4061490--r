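test_that("feature stacking is channel-major with one 40-bin block per channel", {
  set.seed(21)
  arr <- array(rnorm(5 * 4 * 40), dim = c(5, 4, 40))
  psd <- tiny_psd(arr, c("Fz", "Cz", "Pz", "Oz"), freqs = 1:40)
  X1 <- stack_features(psd, "Cz")
  expect_equal(dim(X1), c(5L, 40L))
  expect_equal(unname(X1), arr[, 2, ], ignore_attr = TRUE)
  X4 <- stack_features(psd, c("Fz", "Cz", "Pz", "Oz"))
  expect_equal(dim(X4), c(5L, 160L))
  Xr <- stack_features(psd, c("Oz", "Pz", "Cz", "Fz"))
  expect_equal(unname(Xr[, 1:40]), unname(X4[, 121:160]))
  expect_equal(unname(Xr[, 121:160]), unname(X4[, 1:40]))
  expect_error(stack_features(psd, "nope"), "nope")
})

test_that("variance-retention rule keeps the >= 1% eigenvectors", {
  set.seed(22)
  # rank-1 data: a single latent direction, zero residual
  u <- rnorm(30)
  v <- rnorm(12)
  X <- outer(u, v)
  b <- fit_basis(X)
  expect_equal(ncol(b$V), 1L)
  # exactly isotropic 160-dim noise: every share is 1/160 < 1% -> guard keeps 1
  n <- 201
  Z <- qr.Q(qr(scale(matrix(rnorm(n * n), n), scale = FALSE)))[, 1:160]
  Q <- qr.Q(qr(matrix(rnorm(160 * 160), 160)))
  Xu <- sqrt(n - 1) * Z %*% t(Q)
  bu <- fit_basis(Xu)
  expect_equal(ncol(bu$V), 1L)
  expect_error(fit_basis(matrix(1, 10, 4)), "zero-variance")
})

test_that("planted-spike covariances retain exactly the planted components", {
  set.seed(23)
  d <- 40
  n <- 80
  shares <- c(0.5, 0.3, 0.1, rep(0.1 / (d - 3), d - 3)) # 3 spikes, rest tiny
  lambda <- shares * 100
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  Z <- qr.Q(qr(scale(matrix(rnorm(n * d), n), scale = FALSE)))[, 1:d]
  X <- Z %*% diag(sqrt((n - 1) * lambda)) %*% t(Q)
  b <- fit_basis(X)
  expect_equal(ncol(b$V), 3L)
  # retained eigenvalues match a dense eigen-solver oracle
  e <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(b$lambda[1:3], e$values[1:3], tolerance = 1e-8)
})

test_that("OLS on projections recovers planted coefficients", {
  set.seed(24)
  n <- 400
  X <- matrix(rnorm(n * 20), n)
  X[, 1] <- X[, 1] * 8 # dominant direction
  basis <- fit_basis(X)
  Z <- sweep(X, 2, basis$means) %*% basis$V
  y_exact <- 2.5 * Z[, 1] + 1
  m <- fit_model(X, basis, y_exact)
  expect_equal(m$beta[1], 2.5, tolerance = 1e-8)
  expect_equal(m$intercept, 1, tolerance = 1e-8)
  # constant y: zero coefficients, intercept = mean
  mc <- fit_model(X, basis, rep(3, n))
  expect_equal(mc$beta, rep(0, length(mc$beta)), tolerance = 1e-10)
  expect_equal(mc$intercept, 3)
  # noisy recovery within 3 standard errors
  M <- ncol(basis$V)
  beta_true <- rep(0, M)
  beta_true[seq_len(min(3, M))] <- c(1.5, -2, 0.5)[seq_len(min(3, M))]
  y <- drop(Z %*% beta_true) + rnorm(n, sd = 0.5)
  mn <- fit_model(X, basis, y)
  se <- 0.5 / sqrt(colSums(scale(Z, scale = FALSE)^2))
  expect_true(all(abs(mn$beta - beta_true) < 3.5 * se))
  expect_error(fit_model(X[1:3, ], basis, y[1:3]), "fewer rows")
})

test_that("estimation reproduces training data and matches manual arithmetic", {
  set.seed(25)
  arr <- array(rnorm(30 * 3 * 8), dim = c(30, 3, 8))
  psd <- tiny_psd(arr, c("A", "B", "C"), freqs = 1:8)
  X <- stack_features(psd, c("A", "C"))
  basis <- fit_basis(X)
  Z <- sweep(X, 2, basis$means) %*% basis$V
  y <- drop(Z %*% rnorm(ncol(Z))) + 2
  m <- fit_model(X, basis, y)
  est <- estimate_behavior(m, psd)
  expect_equal(est$values, y, tolerance = 1e-8) # noiseless linear target
  # manual matrix arithmetic oracle
  manual <- drop(sweep(X, 2, basis$means) %*% basis$V %*% m$beta) + m$intercept
  expect_equal(est$values, manual, tolerance = 1e-12)
  # zero-coefficient model gives a constant intercept series
  m0 <- m
  m0$beta <- rep(0, length(m0$beta))
  expect_equal(unique(estimate_behavior(m0, psd)$values), m$intercept)
  expect_error(estimate_behavior(m, tiny_psd(arr[, 1:2, ], c("A", "B"),
                                             freqs = 1:8)), "C")
})

test_that("standard scheme fixes the midline montage and checks channels", {
  set.seed(26)
  arr <- array(rnorm(50 * 5 * 40), dim = c(50, 5, 40))
  psd <- tiny_psd(arr, c("Fz", "Cz", "Pz", "Oz", "X1"), freqs = 1:40)
  y <- rnorm(50)
  m <- fit_standard(psd, y)
  expect_equal(m$channels, c("Fz", "Cz", "Pz", "Oz"))
  expect_equal(length(m$basis$means), 160L)
  psd2 <- tiny_psd(arr[, 1:3, ], c("Fz", "Cz", "Pz"), freqs = 1:40)
  expect_error(fit_standard(psd2, y), "Oz")
})

test_that("training projections are uncorrelated and centering absorbs offsets", {
  set.seed(27)
  arr <- array(rnorm(60 * 2 * 10), dim = c(60, 2, 10))
  psd <- tiny_psd(arr, c("A", "B"), freqs = 1:10)
  X <- stack_features(psd, c("A", "B"))
  basis <- fit_basis(X)
  Z <- sweep(X, 2, basis$means) %*% basis$V
  cz <- crossprod(scale(Z, scale = FALSE))
  off <- cz - diag(diag(cz))
  expect_lt(max(abs(off)), 1e-8)
  # adding a constant to one channel's log power leaves estimates unchanged
  y <- rnorm(60)
  m1 <- fit_model(X, basis, y)
  arr2 <- arr
  arr2[, 1, ] <- arr2[, 1, ] + 5
  psd2 <- tiny_psd(arr2, c("A", "B"), freqs = 1:10)
  X2 <- stack_features(psd2, c("A", "B"))
  b2 <- fit_basis(X2)
  m2 <- fit_model(X2, b2, y)
  expect_equal(estimate_behavior(m2, psd2)$values,
               estimate_behavior(m1, psd)$values, tolerance = 1e-8)
})

test_that("the engine's fit and predictions match the reference path", {
  set.seed(28)
  ps <- planted_session(n_ch = 4, n_blocks = 3, epochs_per_block = 40)
  eng <- perfspec:::build_engine(ps$psd, ps$y)
  fit <- perfspec:::engine_fit(eng, c(1L, 3L), 1:3)
  rows <- seq_along(ps$y)
  pred_engine <- perfspec:::engine_predict(eng, fit, rows)
  X <- stack_features(ps$psd, c("ch1", "ch3"))
  basis <- fit_basis(X)
  m <- fit_model(X, basis, ps$y)
  pred_ref <- estimate_behavior(m, ps$psd)$values
  expect_equal(length(fit$beta), length(m$beta)) # same retention count
  expect_equal(pred_engine, pred_ref, tolerance = 1e-6)
  # the exported model object reproduces the engine predictions
  sm <- perfspec:::as_spectral_model(eng, fit)
  expect_equal(estimate_behavior(sm, ps$psd)$values, pred_engine,
               tolerance = 1e-10)
})

test_that("training RMSE never increases when a retained component is added", {
  set.seed(29)
  n <- 120
  X <- matrix(rnorm(n * 15), n)
  X[, 1:4] <- X[, 1:4] %*% diag(c(10, 8, 6, 4))
  basis <- fit_basis(X)
  Z <- sweep(X, 2, basis$means) %*% basis$V
  y <- rnorm(n)
  rmse <- vapply(seq_len(ncol(Z)), function(m) {
    f <- lm.fit(cbind(1, Z[, seq_len(m), drop = FALSE]), y)
    sqrt(mean(f$residuals^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-12))
})
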