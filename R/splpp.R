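# Sparse locality preserving projections: l1 sparse-reconstruction graph,
# classic k-NN/heat-kernel graph, and the graph-Laplacian generalized
# eigenproblem that yields the linear embedding.

# Nonnegative lasso by cyclic coordinate descent.
# Minimizes ||target - S w||^2 + lambda * sum(w) over w >= 0 with
# w[exclude] pinned at 0. S is p x m (columns are dictionary atoms).
nonneg_lasso_cd <- function(S, target, lambda, exclude = integer(0),
                            tol = 1e-8, max_passes = 1e4) {
  m <- ncol(S)
  g <- colSums(S * S)           # per-atom squared norms
  w <- numeric(m)
  r <- target                   # residual target - S w
  active <- setdiff(seq_len(m), exclude)
  active <- active[g[active] > 0]
  for (pass in seq_len(max_passes)) {
    delta <- 0
    for (j in active) {
      wj_old <- w[j]
      # unconstrained coordinate minimizer, then project onto w >= 0
      wj <- (sum(S[, j] * r) + g[j] * wj_old - lambda / 2) / g[j]
      wj <- max(0, wj)
      if (wj != wj_old) {
        r <- r + S[, j] * (wj_old - wj)
        w[j] <- wj
        delta <- max(delta, abs(wj - wj_old))
      }
    }
    if (delta < tol) break
  }
  w
}

new_sparse_graph <- function(W, symmetrized, builder, lambda_l1 = NA_real_) {
  if (symmetrized) W <- (W + t(W)) / 2
  Dvec <- rowSums(W)
  L <- diag(Dvec, nrow(W)) - W
  structure(
    list(W = W, D = Dvec, L = L, symmetrized = symmetrized,
         lambda_l1 = lambda_l1, builder = builder),
    class = "sparse_graph"
  )
}

#' Sparse reconstruction weight graph
#'
#' For each sample \eqn{x_i}, solves the nonnegative l1 reconstruction
#' problem \eqn{\min_w \|x_i - X w\|^2 + \lambda \|w\|_1} subject to
#' \eqn{w \ge 0} and \eqn{w_i = 0}, so each row of the returned weight
#' matrix expresses the sample as a sparse nonnegative combination of the
#' other samples. The support of each row adapts to the data instead of
#' being fixed by a neighbourhood size.
#'
#' @param X numeric matrix, N samples by p features (rows are samples).
#' @param lambda_l1 nonnegative l1 penalty (default 0.1, calibrated for
#'   \eqn{[-1,1]}-normalized features).
#' @param solver_tol coordinate-descent convergence tolerance on the max
#'   coefficient change per pass.
#' @param max_passes cap on coordinate-descent sweeps per row.
#' @param symmetrize if \code{TRUE} (default) the weight matrix is replaced
#'   by \eqn{(W + W^T)/2} before the degree and Laplacian matrices are
#'   formed, as the embedding eigenproblem presumes symmetric weights.
#' @return a \code{sparse_graph}: \code{W} (N x N, nonnegative, zero
#'   diagonal), degree vector \code{D}, Laplacian \code{L = diag(D) - W},
#'   flags and the penalty used.
#' @export
sparse_reconstruction_weights <- function(X, lambda_l1 = 0.1,
                                          solver_tol = 1e-8,
                                          max_passes = 1e4,
                                          symmetrize = TRUE) {
  stopifnot(is.matrix(X), is.numeric(X))
  n <- nrow(X)
  if (n < 2L) stop("need at least two samples to build a graph")
  if (lambda_l1 < 0) stop("lambda_l1 must be nonnegative")
  S <- t(X)  # p x n dictionary, columns are samples
  if (lambda_l1 == 0 && all(apply(X, 2L, function(col) length(unique(col)) == 1L))) {
    warning("all samples identical and lambda_l1 = 0: reconstruction weights are degenerate")
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, ] <- nonneg_lasso_cd(S, S[, i], lambda_l1, exclude = i,
                              tol = solver_tol, max_passes = max_passes)
  }
  new_sparse_graph(W, symmetrized = symmetrize, builder = "sparse_l1",
                   lambda_l1 = lambda_l1)
}

#' Classic k-nearest-neighbour heat-kernel graph
#'
#' The baseline neighbourhood graph: \eqn{W_{ij} =
#' \exp(-\|x_i - x_j\|^2 / \sigma)} when \eqn{j} is among the k nearest
#' neighbours of \eqn{i} or vice versa, else 0. Symmetric by construction.
#'
#' @param X numeric matrix, N samples by p features.
#' @param k neighbourhood size, \code{1 <= k < N}.
#' @param sigma positive heat-kernel bandwidth.
#' @return a \code{sparse_graph}.
#' @export
knn_heat_weights <- function(X, k, sigma) {
  stopifnot(is.matrix(X), is.numeric(X))
  n <- nrow(X)
  if (k < 1L || k >= n) stop(sprintf("k must satisfy 1 <= k < N = %d", n))
  if (sigma <= 0) stop("sigma must be positive")
  d2 <- as.matrix(stats::dist(X))^2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    W[i, nb] <- exp(-d2[i, nb] / sigma)
  }
  # mutual or-rule: keep an edge if either endpoint selected it
  W <- pmax(W, t(W))
  diag(W) <- 0
  new_sparse_graph(W, symmetrized = TRUE, builder = "knn_heat")
}

#' Locality preserving projection from a weight graph
#'
#' Solves the generalized eigenproblem \eqn{X L X^T a = \lambda X D X^T a}
#' (samples as columns of \eqn{X}) and returns the \code{d} eigenvectors of
#' smallest nonzero eigenvalue, each scaled so that
#' \eqn{a^T (X D X^T + ridge I) a = 1}. Near-zero eigenvalues (below
#' \code{1e-10} of the largest) correspond to degenerate directions and are
#' discarded before the smallest \code{d} are taken.
#'
#' @param X numeric matrix, N samples by p features (rows are samples; the
#'   transpose is used internally to match the column-sample convention).
#' @param graph a \code{sparse_graph} built on the same N samples; must be
#'   symmetrized.
#' @param d embedding dimension, \code{d <= p}.
#' @param ridge relative ridge added to \eqn{X D X^T} as
#'   \code{ridge * trace(XDX^T)/p * I}, making the right-hand side positive
#'   definite when p exceeds N. Default \code{1e-6}; use 0 only on
#'   full-rank problems.
#' @return a \code{lpp_projection}: \code{A} (p x d), \code{eigenvalues}
#'   (ascending), \code{d} and the absolute ridge used.
#' @export
lpp_project <- function(X, graph, d, ridge = 1e-6) {
  stopifnot(is.matrix(X), inherits(graph, "sparse_graph"))
  n <- nrow(X); p <- ncol(X)
  if (nrow(graph$W) != n) stop("graph was built on a different sample count")
  if (!graph$symmetrized) stop("graph must be symmetrized before projection")
  if (d < 1L || d > p) stop(sprintf("d must be in 1..%d", p))
  M <- t(X)  # p x n, columns are samples
  C <- M %*% graph$L %*% t(M)
  C <- (C + t(C)) / 2
  B <- M %*% (graph$D * t(M))
  B <- (B + t(B)) / 2
  ridge_abs <- if (ridge > 0) ridge * sum(diag(B)) / p else 0
  if (ridge_abs > 0) B <- B + diag(ridge_abs, p)
  U <- tryCatch(chol(B), error = function(e) {
    stop("X D X^T is singular; use a positive ridge (", conditionMessage(e), ")")
  })
  Ui <- backsolve(U, diag(p))
  K <- crossprod(Ui, C) %*% Ui
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)  # descending
  vals <- rev(eig$values)
  vecs <- eig$vectors[, ncol(eig$vectors):1, drop = FALSE]
  thr <- 1e-10 * max(abs(vals), 1e-300)
  keep <- which(vals > thr)
  if (length(keep) < d) {
    stop(sprintf(
      "requested d = %d but only %d non-degenerate directions attainable",
      d, length(keep)
    ))
  }
  sel <- keep[seq_len(d)]
  A <- Ui %*% vecs[, sel, drop = FALSE]  # columns satisfy a' B a = 1
  structure(
    list(A = A, eigenvalues = vals[sel], d = d, ridge = ridge_abs),
    class = "lpp_projection"
  )
}

#' Apply a learned linear embedding
#'
#' Maps each row \eqn{x_i} to \eqn{y_i = A^T x_i}.
#'
#' @param projection a \code{lpp_projection}.
#' @param X numeric matrix (or single vector) with p columns.
#' @return N x d embedded matrix.
#' @export
lpp_transform <- function(projection, X) {
  stopifnot(inherits(projection, "lpp_projection"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != nrow(projection$A)) {
    stop(sprintf(
      "dimension mismatch: projection expects %d features, got %d",
      nrow(projection$A), ncol(X)
    ))
  }
  X %*% projection$A
}

#' @export
print.sparse_graph <- function(x, ...) {
  nz <- sum(x$W > 0)
  cat(sprintf(
    "sparse_graph (%s): %d nodes, %d nonzero weights%s%s\n",
    x$builder, nrow(x$W), nz,
    if (x$symmetrized) ", symmetrized" else "",
    if (!is.na(x$lambda_l1)) sprintf(", lambda_l1=%g", x$lambda_l1) else ""
  ))
  invisible(x)
}

#' @export
print.lpp_projection <- function(x, ...) {
  cat(sprintf(
    "lpp_projection: %d -> %d, eigenvalues [%s], ridge %.3g\n",
    nrow(x$A), x$d, paste(sprintf("%.3g", x$eigenvalues), collapse = ", "),
    x$ridge
  ))
  invisible(x)
}
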