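test_that("standardization round-trips and masks constant columns", {
  set.seed(1)
  X <- cbind(matrix(rnorm(40), 10), const = rep(3, 10))
  s <- standardizeColumns(X)
  expect_equal(unname(colMeans(s$X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(s$X[, 1:4], 2, sd)), rep(1, 4),
               tolerance = 1e-12)
  expect_true(s$constMask[5])
  expect_equal(s$X[, 5], rep(0, 10))
  back <- lvmap:::destandardizeColumns(s$X, s$center, s$scale)
  expect_equal(back, X, tolerance = 1e-10)
  expect_equal(standardizeColumns(matrix(1:3, 3))$X[, 1],
               c(-1, 0, 1), tolerance = 1e-12)
})

test_that("the identity task is reproduced with full rank", {
  set.seed(2)
  X <- matrix(rnorm(10 * 6), 10, 6)
  m <- fitPls(X, X, 6)
  expect_equal(predict(m, X), X, tolerance = 1e-6)
})

test_that("a single shared latent factor matches the closed-form rank-1 fit", {
  set.seed(3)
  tscore <- rnorm(15)
  X <- outer(tscore, rnorm(7))
  Y <- outer(tscore, rnorm(5))
  m <- fitPls(X, Y, 1)
  # closed-form oracle via the SVD of the standardized X: the rank-1
  # least-squares fit of standardized Y on the first left singular vector
  sx <- standardizeColumns(X); sy <- standardizeColumns(Y)
  u1 <- svd(sx$X)$u[, 1]
  yhatS <- outer(u1, drop(crossprod(u1, sy$X)))
  oracle <- lvmap:::destandardizeColumns(yhatS, sy$center, sy$scale)
  expect_equal(predict(m, X), oracle, tolerance = 1e-8)
})

test_that("predictions agree with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  for (r in 1:5) {
    n <- sample(15:30, 1)
    px <- sample(8:20, 1); py <- sample(5:15, 1)
    k <- sample(1:4, 1)
    L <- matrix(rnorm(n * 5), n, 5)
    X <- L %*% matrix(rnorm(5 * px), 5, px) + 0.2 * matrix(rnorm(n * px), n, px)
    Y <- L %*% matrix(rnorm(5 * py), 5, py) + 0.2 * matrix(rnorm(n * py), n, py)
    colnames(X) <- paste0("x", seq_len(px))
    colnames(Y) <- paste0("y", seq_len(py))
    m <- fitPls(X, Y, k)
    ref <- mixOmics::pls(X, Y, ncomp = k, mode = "regression", scale = TRUE)
    yh <- predict(m, X)
    yo <- predict(ref, X)$predict[, , k]
    expect_lt(max(abs(yh - yo)), 1e-6)
  }
})

test_that("training X-scores are mutually orthogonal", {
  set.seed(5)
  X <- matrix(rnorm(25 * 12), 25, 12)
  Y <- X[, 1:6] + 0.3 * matrix(rnorm(25 * 6), 25, 6)
  m <- fitPls(X, Y, 5)
  G <- crossprod(m@scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("prediction is affine in the inputs", {
  set.seed(6)
  X <- matrix(rnorm(20 * 10), 20, 10)
  Y <- X %*% matrix(rnorm(10 * 4), 10, 4) + 0.1 * matrix(rnorm(20 * 4), 20, 4)
  m <- fitPls(X, Y, 3)
  x1 <- X[1, ]; x2 <- X[2, ]
  for (aWt in c(0.25, 0.5, 0.8)) {
    lhs <- predict(m, aWt * x1 + (1 - aWt) * x2)
    rhs <- aWt * predict(m, x1) + (1 - aWt) * predict(m, x2)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
  # centering property: the training X mean maps to the training Y mean
  expect_equal(drop(predict(m, colMeans(X))), colMeans(Y), tolerance = 1e-8)
  # consistency: a training row predicts its fitted value
  expect_equal(predict(m, X[3, , drop = FALSE]), predict(m, X)[3, , drop = FALSE],
               tolerance = 1e-12)
  expect_error(predict(m, matrix(0, 1, 7)), "column count")
})

test_that("full-component PLS equals ordinary least squares on tall problems", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- X %*% matrix(rnorm(5 * 3), 5, 3) + 0.5 * matrix(rnorm(30 * 3), 30, 3)
  m <- fitPls(X, Y, 5)
  ols <- stats::lm(Y ~ X)
  expect_equal(unname(predict(m, X)), unname(stats::fitted(ols)),
               tolerance = 1e-6)
})

test_that("cross-validated component selection finds the true model order", {
  set.seed(8)
  # noiseless single factor
  tscore <- rnorm(30)
  X1 <- outer(tscore, rnorm(8))
  Y1 <- outer(tscore, rnorm(6))
  expect_equal(selectComponents(X1, Y1, kMax = 4)$nComponents, 1L)
  # three strong factors, weak noise
  L <- matrix(rnorm(40 * 3), 40, 3)
  X3 <- L %*% matrix(rnorm(3 * 12), 3, 12) + 0.01 * matrix(rnorm(40 * 12), 40, 12)
  Y3 <- L %*% matrix(rnorm(3 * 9), 3, 9) + 0.01 * matrix(rnorm(40 * 9), 40, 9)
  sel <- selectComponents(X3, Y3, kMax = 6, foldSeed = 2)
  expect_equal(sel$nComponents, 3L)
  # determinism under a fixed fold seed
  sel2 <- selectComponents(X3, Y3, kMax = 6, foldSeed = 2)
  expect_identical(sel$nComponents, sel2$nComponents)
  expect_identical(sel$cvMse, sel2$cvMse)
  expect_error(selectComponents(X3[1:3, ], Y3[1:3, ], folds = 5), "folds")
})

test_that("leave-one-out on a degenerate population has zero error", {
  row <- rnorm(12)
  X <- matrix(rep(row, 6), 6, byrow = TRUE)
  Y <- matrix(rep(rnorm(9), 6), 6, byrow = TRUE)
  loo <- looPredict(X, Y, nComponents = 2)
  expect_equal(loo$predictions, Y, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(nrow(loo$predictions), 6L)
})

test_that("nComponents bounds are enforced", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fitPls(X, X, 0), ">= 1")
  expect_error(fitPls(X, X, 4), "exceeds")
  expect_error(fitPls(X, X[1:3, ], 1), "same number of rows")
})
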