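test_that("sparse reconstruction rows reach the grid-oracle optimum on 3-sample toys", {
  set.seed(31)
  for (rep_ in 1:5) {
    X <- matrix(runif(6, -1, 1), 3, 2)
    lambda <- 0.1
    g <- sparse_reconstruction_weights(X, lambda_l1 = lambda, symmetrize = FALSE)
    S <- t(X)
    for (i in 1:3) {
      free <- setdiff(1:3, i)
      obj <- nn_lasso_objective(S, S[, i], lambda, g$W[i, ])
      best <- oracle_nn_lasso_objective(S, S[, i], lambda, free)
      expect_lte(obj, best + 1e-6)
    }
  }
})

test_that("weight rows are nonnegative with exactly zero self-weight; duplicates concentrate weight", {
  set.seed(32)
  # high dimension: only the duplicate can reconstruct row 1 exactly
  X <- matrix(rnorm(60), 6, 10)
  X[3, ] <- X[1, ]
  g <- sparse_reconstruction_weights(X, lambda_l1 = 0.01, symmetrize = FALSE)
  expect_true(all(g$W >= 0))
  expect_true(all(diag(g$W) == 0))
  # row 1 reconstructs itself from its duplicate with near-zero residual
  resid <- X[1, ] - as.vector(g$W[1, ] %*% X)
  expect_lt(sum(resid^2), 1e-3)
  expect_gt(g$W[1, 3], 0.8)
})

test_that("a huge l1 penalty drives all weights to zero; negative penalties are rejected", {
  set.seed(33)
  X <- matrix(runif(12, -1, 1), 4, 3)
  g <- sparse_reconstruction_weights(X, lambda_l1 = 1e6)
  expect_true(all(g$W == 0))
  expect_error(sparse_reconstruction_weights(X, lambda_l1 = -1), "nonnegative")
})

test_that("with a positive penalty the graph is sparser than complete on generic data", {
  set.seed(34)
  X <- matrix(rnorm(30 * 5), 30, 5)
  g <- sparse_reconstruction_weights(X, lambda_l1 = 0.1, symmetrize = FALSE)
  mean_support <- mean(rowSums(g$W > 0))
  expect_lt(mean_support, nrow(X) - 1)
})

test_that("graph bookkeeping: degrees equal row sums, symmetrized Laplacian rows sum to 0 and L is PSD", {
  set.seed(35)
  X <- matrix(rnorm(16 * 4), 16, 4)
  g <- sparse_reconstruction_weights(X, lambda_l1 = 0.05)
  expect_true(g$symmetrized)
  expect_equal(g$W, t(g$W))
  expect_equal(g$D, rowSums(g$W))
  expect_equal(rowSums(g$L), rep(0, 16), tolerance = 1e-12)
  for (i in 1:20) {
    v <- rnorm(16)
    expect_gte(drop(t(v) %*% g$L %*% v), -1e-10)
  }
})

test_that("knn heat graph: zero distance gives weight 1, k=N-1 completes the graph, sigma is monotone", {
  X <- rbind(c(0, 0), c(0, 0), c(3, 4))
  g <- knn_heat_weights(X, k = 1L, sigma = 1)
  expect_equal(g$W[1, 2], 1)
  g_full <- knn_heat_weights(X, k = 2L, sigma = 10)
  expect_true(all(g_full$W[upper.tri(g_full$W)] > 0))
  expect_true(all(diag(g_full$W) == 0))
  g_small <- knn_heat_weights(X, k = 2L, sigma = 5)
  expect_true(all(g_full$W >= g_small$W))
  expect_error(knn_heat_weights(X, k = 3L, sigma = 1), "k must")
})

test_that("embedding objective identity: sum_ij ||y_i - y_j||^2 W_ij = 2 tr(A' X L X' A)", {
  set.seed(36)
  X <- matrix(rnorm(20 * 4), 20, 4)
  g <- sparse_reconstruction_weights(X, lambda_l1 = 0.05)
  proj <- lpp_project(X, g, d = 2L, ridge = 1e-6)
  Y <- lpp_transform(proj, X)
  lhs <- 0
  for (i in 1:20) for (j in 1:20) {
    lhs <- lhs + sum((Y[i, ] - Y[j, ])^2) * g$W[i, j]
  }
  M <- t(X)
  rhs <- 2 * sum(diag(t(proj$A) %*% M %*% g$L %*% t(M) %*% proj$A))
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("generalized eigenpairs satisfy the defining residual at ridge = 0 on a full-rank toy", {
  set.seed(37)
  X <- matrix(rnorm(30 * 4), 30, 4)  # N > p keeps X D X' full rank
  g <- knn_heat_weights(X, k = 4L, sigma = 2)
  proj <- lpp_project(X, g, d = 3L, ridge = 0)
  M <- t(X)
  C <- M %*% g$L %*% t(M)
  B <- M %*% (g$D * t(M))
  for (k in 1:3) {
    a <- proj$A[, k]
    lam <- proj$eigenvalues[k]
    resid <- sqrt(sum((C %*% a - lam * B %*% a)^2)) / sqrt(sum((C %*% a)^2))
    expect_lt(resid, 1e-6)
    expect_equal(drop(t(a) %*% B %*% a), 1, tolerance = 1e-8)
  }
  expect_true(all(diff(proj$eigenvalues) >= -1e-12))
})

test_that("transform is the linear map A^T x: identity projection, single points, linearity", {
  p <- 3L
  proj <- structure(list(A = diag(p), eigenvalues = rep(0, p), d = p, ridge = 0),
                    class = "lpp_projection")
  X <- matrix(rnorm(12), 4, 3)
  expect_identical(lpp_transform(proj, X), X %*% diag(p))
  a1 <- matrix(c(1, 2, -1), 3, 1)
  proj1 <- structure(list(A = a1, eigenvalues = 0, d = 1L, ridge = 0),
                     class = "lpp_projection")
  x <- c(0.5, -1, 2)
  expect_equal(drop(lpp_transform(proj1, x)), sum(a1 * x))
  x2 <- rnorm(3)
  lhs <- lpp_transform(proj1, 2 * x + 3 * x2)
  rhs <- 2 * lpp_transform(proj1, x) + 3 * lpp_transform(proj1, x2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(lpp_transform(proj1, matrix(0, 2, 4)), "mismatch")
})

test_that("duplicated inputs receive identical embeddings", {
  set.seed(38)
  X <- matrix(rnorm(15 * 3), 15, 3)
  X[7, ] <- X[2, ]
  g <- sparse_reconstruction_weights(X, lambda_l1 = 0.05)
  proj <- lpp_project(X, g, d = 2L)
  Y <- lpp_transform(proj, X)
  expect_equal(Y[7, ], Y[2, ], tolerance = 1e-12)
})

test_that("unattainable embedding dimensions are refused with the attainable count", {
  set.seed(39)
  X <- matrix(rnorm(4 * 6), 4, 6)  # p > N: rank-deficient pencil
  g <- sparse_reconstruction_weights(X, lambda_l1 = 0.05)
  expect_error(lpp_project(X, g, d = 6L, ridge = 1e-6), "attainable")
  expect_error(lpp_project(X, g, d = 7L), "1\\.\\.6")
})
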