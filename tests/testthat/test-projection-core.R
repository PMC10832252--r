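test_that("one projection pass gives the stated score, loading and deflation", {
  X <- matrix(c(2, -2, 0, 0, 0, 0, 1, -1), 4, 2)
  res <- project_component(X, c(1, 0))
  expect_equal(res$t, c(2, -2, 0, 0))
  expect_equal(res$p, c(1, 0))
  expect_equal(res$X_next[, 1], rep(0, 4))
  expect_equal(res$X_next[, 2], X[, 2])

  # rank-1 matrix deflates to zero along its dominant direction
  u <- c(1, 2, -1, 0.5); v <- c(2, -1, 1)
  X1 <- outer(u - mean(u), v)
  w <- svd(X1)$v[, 1]
  expect_lt(max(abs(project_component(X1, w)$X_next)), 1e-12)

  # residual is orthogonal to the score for random input
  set.seed(4)
  X2 <- rand_centred(6, 4)
  w2 <- rnorm(4); w2 <- w2 / sqrt(sum(w2^2))
  r2 <- project_component(X2, w2)
  expect_lt(max(abs(crossprod(r2$X_next, r2$t))), 1e-10)

  expect_error(project_component(X2, c(1, 0, 0, 0, 0)), "length")
  expect_error(project_component(X2, rep(0.5, 4) * 2), "unit length")
})

test_that("power-iteration PCA matches the SVD oracle", {
  for (seed in 1:3) {
    X <- rand_centred(30, 6, seed = seed)
    A <- 4
    fit <- pca_nipals(X, A)
    sv <- svd(X)
    expect_equal(fit$ess, sv$d[1:A]^2, tolerance = 1e-8)
    for (a in 1:A) {
      # loadings equal right singular vectors up to sign
      align <- sign(sum(fit$W[, a] * sv$v[, a]))
      expect_equal(fit$W[, a], align * sv$v[, a], tolerance = 1e-6)
    }
    # scores orthogonal, weights unit length
    G <- crossprod(fit$T)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
    expect_equal(colSums(fit$W^2), rep(1, A), tolerance = 1e-10)
  }
})

test_that("PCA on diagonal-covariance data returns sorted column variances", {
  set.seed(12)
  X <- cbind(3 * rnorm(2000), 2 * rnorm(2000), rnorm(2000))
  X <- sweep(X, 2, colMeans(X))
  fit <- pca_nipals(X, 3)
  expect_equal(fit$ess / nrow(X), sort(apply(X, 2, var), decreasing = TRUE),
               tolerance = 0.15)
  # an exactly isotropic pair is flagged as a degenerate subspace
  Xd <- rbind(diag(c(2, 2)), -diag(c(2, 2)))
  fitd <- pca_nipals(sweep(Xd, 2, colMeans(Xd)), 2)
  expect_true(fitd$degenerate[2])
})

test_that("PLS1 reduces to known closed forms", {
  set.seed(21)
  # single predictor: b is the simple regression slope
  x <- matrix(rnorm(40), ncol = 1); x <- x - mean(x)
  y <- 2 * x[, 1] + rnorm(40); y <- y - mean(y)
  fit1 <- pls1(x, y, 1)
  expect_equal(fit1$b, sum(x * y) / sum(x^2), tolerance = 1e-12)

  # orthonormal design, A = V: b = X'y
  Q <- qr.Q(qr(rand_centred(20, 5, seed = 2)))
  Q <- sweep(Q, 2, colMeans(Q))   # still near-orthogonal after centring? enforce:
  Q <- qr.Q(qr(Q))
  yq <- rnorm(20); yq <- yq - mean(yq)
  # an orthonormal design is exhausted after one component (X2'y = 0),
  # and the single-component b already equals X'y
  expect_warning(fitq <- pls1(Q, yq, 5), "truncated")
  expect_equal(unname(fitq$b), drop(crossprod(Q, yq)), tolerance = 1e-6)
})

test_that("full-component PLS1 equals least squares (normal-equations oracle)", {
  for (seed in 1:3) {
    d <- rand_xy(20, 5, seed = seed)
    fit <- pls1(d$X, d$y, 5)
    b_ls <- drop(solve(crossprod(d$X), crossprod(d$X, d$y)))
    expect_equal(fit$b, b_ls, tolerance = 1e-8)
    expect_equal(drop(d$X %*% fit$b), drop(fit$T %*% fit$q), tolerance = 1e-8)
  }
})

test_that("PLS1 explained outcome variance is non-decreasing in A", {
  d <- rand_xy(50, 8, seed = 5, noise = 2)
  fit <- pls1(d$X, d$y, 8)
  expect_true(all(fit$ess_y >= -1e-12))
  expect_true(all(diff(cumsum(fit$ess_y)) >= -1e-10))
})

test_that("PLS1 stops cleanly when the covariance vanishes", {
  # X orthogonal to y: no component at all
  X <- matrix(c(1, -1, 0, 0, 0, 0, 1, -1), 4, 2)
  y <- c(1, 1, -1, -1)
  expect_error(pls1(X, y, 1), "no predictive component")
  # rank-1 X: second component request is truncated with a warning
  X1 <- outer(c(1, -1, 2, -2), c(1, 2)); X1 <- sweep(X1, 2, colMeans(X1))
  y1 <- X1[, 1]
  expect_warning(fit <- pls1(X1, y1, 3), "truncated")
  expect_equal(fit$A, 1L)
})

test_that("target projection carries all predictive variance in one component", {
  for (seed in 1:3) {
    d <- rand_xy(40, 6, seed = seed, noise = 1)
    fit <- pls1(d$X, d$y, 4)
    tp <- target_projection(fit, d$X)
    # score collinear with the PLS fitted values
    yh <- drop(d$X %*% fit$b)
    expect_equal(abs(cor(tp$t, yh)), 1, tolerance = 1e-8)
    # predictive y-variance preserved exactly
    expect_equal(tp$explained_y_fraction, fit$explained_y_fraction,
                 tolerance = 1e-8)
    # variance of fitted values identical between TP and PLS routes
    expect_equal(var(tp$t * tp$q), var(drop(fit$T %*% fit$q)), tolerance = 1e-8)
    expect_true(tp$explained_X_fraction >= 0 && tp$explained_X_fraction <= 1)
    # orientation: target score points along the predicted outcome
    expect_gte(cor(tp$t, yh), 0)
  }
  # one-component model: TP is that component up to sign
  d <- rand_xy(30, 5, seed = 9)
  f1 <- pls1(d$X, d$y, 1)
  tp1 <- target_projection(f1, d$X)
  expect_equal(abs(cor(tp1$t, f1$T[, 1])), 1, tolerance = 1e-10)
})

test_that("covariate projection equals simple-regression residuals", {
  set.seed(31)
  M <- rand_centred(25, 6)
  colnames(M) <- c("y", "z", paste0("x", 1:4))
  res <- covariate_project(M, "z")
  for (cl in colnames(M)) {
    if (cl == "z") { expect_equal(unname(res$M[, cl]), rep(0, 25)); next }
    lmres <- residuals(lm(M[, cl] ~ M[, "z"] - 1))
    expect_equal(unname(res$M[, cl]), unname(lmres), tolerance = 1e-10)
  }
  # collinear case zeroes the column
  M2 <- cbind(y = c(2, -2), z = c(1, -1))
  expect_equal(unname(covariate_project(M2, "z")$M[, "y"]), c(0, 0))
  # orthogonal column unchanged
  M3 <- cbind(z = c(1, -1, 1, -1), u = c(1, 1, -1, -1))
  expect_equal(covariate_project(M3, "z")$M[, "u"], M3[, "u"])
})

test_that("covariate projections commute for uncorrelated covariates and are exhaustive", {
  set.seed(41)
  z1 <- rep(c(1, -1), 10)
  z2 <- rep(c(1, 1, -1, -1), 5)   # orthogonal to z1
  X <- rand_centred(20, 3)
  M <- cbind(z1 = z1, z2 = z2, X)
  ab <- covariate_project(covariate_project(M, "z1")$M, "z2")$M
  ba <- covariate_project(covariate_project(M, "z2")$M, "z1")$M
  expect_equal(ab, ba, tolerance = 1e-10)
  # projecting again on the exhausted covariate is an error
  expect_error(covariate_project(ab, "z1"), "zero-variance")
  # projecting on a fresh copy of the same covariate changes nothing
  M4 <- cbind(ab, z1b = z1 - mean(z1))
  again <- covariate_project(M4, "z1b")$M
  expect_equal(again[, colnames(ab)], ab, tolerance = 1e-10)
})

test_that("sequential projection on orthogonalised covariates equals MLR residuals", {
  set.seed(51)
  n <- 40
  Z <- rand_centred(n, 3)
  X <- rand_centred(n, 4)
  y <- rnorm(n); y <- y - mean(y)
  # Gram-Schmidt orthogonalise the covariates, then project sequentially
  Zo <- qr.Q(qr(Z)) * sqrt(n)
  M <- cbind(y = y, z1 = Zo[, 1], z2 = Zo[, 2], z3 = Zo[, 3], X)
  for (z in c("z1", "z2", "z3")) M <- covariate_project(M, z)$M
  fitted_cols <- cbind(y, X)
  for (j in seq_len(ncol(fitted_cols))) {
    r <- residuals(lm(fitted_cols[, j] ~ Z))
    expect_equal(unname(M[, c("y", paste0("x", 1:4))[j]]), unname(r),
                 tolerance = 1e-10)
  }
})
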