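test_that("mlr_fit solves small exact problems", {
  fit <- mlr_fit(matrix(c(1, 2, 3), ncol = 1), c(2, 4, 6))
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  X <- matrix(rnorm(20), 10, 2)
  fit2 <- mlr_fit(X, rep(7, 10))
  expect_equal(unname(fit2$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(fit2$intercept, 7, tolerance = 1e-10)
})

test_that("mlr_fit matches the normal-equations oracle on random problems", {
  set.seed(7)
  for (rep in 1:50) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- X %*% rnorm(5) + rnorm(30)
    fit <- mlr_fit(X, y)
    expect_equal(c(fit$intercept, unname(fit$coefficients)),
                 oracle_ols(X, y), tolerance = 1e-8)
    # contract: residuals orthogonal to the design
    res <- y - predict(fit, X)
    expect_lt(max(abs(crossprod(cbind(1, X), res))), 1e-8)
  }
})

test_that("mlr_fit rejects under-determined and collinear designs", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(mlr_fit(X, rnorm(4)), "more samples")
  X2 <- matrix(rnorm(40), 20, 2)
  X2 <- cbind(X2, dup = X2[, 1])
  colnames(X2) <- c("b1", "b2", "dup")
  expect_error(mlr_fit(X2, rnorm(20)), "dup")
})

test_that("plsr_fit with full components reproduces OLS predictions", {
  set.seed(8)
  for (rep in 1:10) {
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- as.vector(X %*% rnorm(6) + rnorm(30))
    mlr <- mlr_fit(X, y)
    pls <- plsr_fit(X, y, n_components = 6)
    expect_equal(predict(pls, X), predict(mlr, X), tolerance = 1e-8)
  }
})

test_that("plsr_fit single-column case collapses to simple regression", {
  set.seed(9)
  x <- matrix(rnorm(25), ncol = 1)
  y <- as.vector(2.5 * x + 1 + rnorm(25, sd = 0.3))
  pls <- plsr_fit(x, y, 1)
  ols <- oracle_ols(x, y)
  expect_equal(c(pls$intercept, unname(pls$coefficients)), ols,
               tolerance = 1e-8)
})

test_that("NIPALS produces orthogonal scores that reproduce X", {
  set.seed(10)
  Q <- qr.Q(qr(matrix(rnorm(40 * 4), 40, 4)))  # orthonormal columns
  y <- as.vector(Q %*% c(3, -1, 2, 0.5) + rnorm(40, sd = 0.05))
  pls <- plsr_fit(Q, y, 3)
  G <- crossprod(pls$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # scores lie in the column space: T = E0 W(P'W)^-1 reproduces them
  E0 <- scale(Q, scale = FALSE)
  R <- pls$W %*% solve(crossprod(pls$P, pls$W))
  expect_equal(unname(E0 %*% R), unname(pls$T), tolerance = 1e-8)
})

test_that("plsr_fit input guards", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(plsr_fit(X, rep(1, 10), 1), "zero variance")
  expect_error(plsr_fit(X, rnorm(10), 5), "n_components")
})

test_that("select_plsr_components scans every allowed count", {
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.vector(X[, 1:2] %*% c(2, -1) + rnorm(40, sd = 0.2))
  pick <- select_plsr_components(X[1:25, ], y[1:25], X[-(1:25), ], y[-(1:25)])
  expect_equal(pick$path$n_components, 1:6)
  expect_equal(pick$n_components, which.min(pick$path$rmse))
  expect_equal(pick$model$n_components, pick$n_components)
})

test_that("predict applies the stored linear map deterministically", {
  set.seed(12)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- as.vector(X %*% c(1, 2, 3) + 4)
  fit <- mlr_fit(X, y)
  pred <- predict(fit, X)
  expect_equal(mean(y - pred), 0, tolerance = 1e-10)
  expect_identical(predict(fit, X[c(5, 5), ])[1], predict(fit, X[c(5, 5), ])[2])
  expect_error(predict(fit, X[, 1:2]), "bands")
})

test_that("score reproduces the hand-computed metric cases", {
  y <- c(10, 20, 30, 40)
  perfect <- score(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  null_model <- score(y, rep(mean(y), 4))
  expect_equal(null_model$r2, 0)

  expect_equal(score(c(0, 0), c(3, 4))$rmse, sqrt(12.5))
  expect_true(is.na(score(c(5, 5), c(3, 4))$r2))
  expect_equal(score(c(5, 5), c(3, 4))$rmse, sqrt(mean(c(4, 1))))
  expect_error(score(1:3, 1:2), "lengths differ")
})

test_that("score is invariant under sample permutation", {
  set.seed(13)
  y <- rnorm(20); yh <- y + rnorm(20, sd = 0.5)
  p <- sample(20)
  expect_equal(score(y, yh), score(y[p], yh[p]))
})

test_that("training R2 is non-decreasing in nested MLR models", {
  set.seed(14)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.vector(X %*% rnorm(6) + rnorm(40))
  r2 <- vapply(1:6, function(p) {
    fit <- mlr_fit(X[, 1:p, drop = FALSE], y)
    fit$train_score$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("tidy and glance summarise fitted models", {
  set.seed(15)
  X <- matrix(rnorm(30 * 3), 30, 3)
  colnames(X) <- c("702", "731", "955")
  y <- as.vector(X %*% c(1, -2, 0.5) + 40 + rnorm(30, sd = 0.1))
  fit <- mlr_fit(X, y)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "702", "731", "955"))
  expect_equal(td$estimate[-1], unname(fit$coefficients))
  gl <- glance(fit)
  expect_equal(gl$kind, "mlr")
  expect_equal(gl$n_bands, 3)
  gl2 <- glance(plsr_fit(X, y, 2))
  expect_equal(gl2$n_components, 2)
})
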