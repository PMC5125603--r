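# Independent oracles and small fixture builders used across the suite.
# Every oracle is deliberately naive (enumeration, grids, direct algebra)
# and shares no code with the implementation paths it checks.

# Direct mixture emission density (linear-space naive arithmetic).
oracle_emission_density <- function(model, frame, state) {
  total <- 0
  for (m in seq_len(model$M)) {
    comp <- model$mix_weights[state, m]
    for (o in seq_len(model$O)) {
      comp <- comp * stats::dnorm(frame[o], model$means[state, m, o],
                                  sqrt(model$variances[state, m, o]))
    }
    total <- total + comp
  }
  total
}

# Brute-force sequence likelihood: enumerate all Q^T hidden state paths.
oracle_path_loglik <- function(model, sequence) {
  Tn <- nrow(sequence)
  Q <- model$Q
  paths <- expand.grid(rep(list(seq_len(Q)), Tn))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- as.integer(paths[r, ])
    pr <- model$pi[path[1L]]
    if (Tn > 1L) {
      for (t in 2:Tn) pr <- pr * model$trans[path[t - 1L], path[t]]
    }
    for (t in seq_len(Tn)) {
      pr <- pr * oracle_emission_density(model, sequence[t, ], path[t])
    }
    total <- total + pr
  }
  log(total)
}

# Random valid CHMM with given dimensions (uses the current RNG state).
random_chmm <- function(Q, M, O, floor = 1e-3) {
  rdirich <- function(n) { x <- stats::runif(n, 0.2, 1); x / sum(x) }
  trans <- t(vapply(seq_len(Q), function(i) rdirich(Q), numeric(Q)))
  mixw <- t(vapply(seq_len(Q), function(i) rdirich(M), numeric(M)))
  model <- structure(
    list(Q = Q, M = M, O = O,
         pi = rdirich(Q),
         trans = matrix(trans, Q, Q),
         mix_weights = matrix(mixw, Q, M),
         means = array(stats::rnorm(Q * M * O, sd = 1.5), c(Q, M, O)),
         variances = array(stats::runif(Q * M * O, 0.05, 1.5), c(Q, M, O)),
         variance_floor = floor),
    class = "chmm"
  )
  validate_chmm(model)
  model
}

# Grid-search oracle for the per-row nonnegative l1 reconstruction
# objective ||x - S w||^2 + lambda * sum(w): exhaustive over a fine grid
# on the free coordinates (only feasible for <= 2 free weights).
oracle_nn_lasso_objective <- function(S, x, lambda, free, wmax = 3,
                                      step = 0.002) {
  grid <- seq(0, wmax, by = step)
  best <- Inf
  if (length(free) == 1L) {
    for (w1 in grid) {
      r <- x - S[, free[1L]] * w1
      best <- min(best, sum(r * r) + lambda * w1)
    }
  } else if (length(free) == 2L) {
    for (w1 in grid) {
      r1 <- x - S[, free[1L]] * w1
      for (w2 in grid) {
        r <- r1 - S[, free[2L]] * w2
        best <- min(best, sum(r * r) + lambda * (w1 + w2))
      }
    }
  } else {
    stop("oracle supports at most 2 free weights")
  }
  best
}

nn_lasso_objective <- function(S, x, lambda, w) {
  r <- x - S %*% w
  sum(r * r) + lambda * sum(w)
}

# Univariate mutual-information ranking oracle (equal-width binning).
oracle_mi_ranking <- function(X, y, bins = 8L) {
  mi_one <- function(x) {
    bx <- cut(x, breaks = bins, labels = FALSE)
    tab <- table(bx, y)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
    s
  }
  apply(X, 2L, mi_one)
}

# Best-permutation parameter matching for a fitted 2-state model against
# the generating truth: returns the state order minimizing mean |mean diff|.
match_states_2 <- function(fit_means, true_means) {
  d_id <- mean(abs(fit_means - true_means))
  d_sw <- mean(abs(fit_means[2:1, , , drop = FALSE] - true_means))
  if (d_id <= d_sw) 1:2 else 2:1
}

# Small labeled dataset builder.
toy_dataset <- function(X, y, names = sprintf("tBodyAcc-f%d", seq_len(ncol(X))),
                        split = "unsplit") {
  har_dataset(X, y, names, split = split)
}

# Shared small synthetic pipeline fixture for structural hierarchy tests:
# reduced sizes keep repeated training cheap.
small_pipeline_config <- function() {
  tschmm_config(
    rfim = list(ntree = 150L),
    em = list(max_iter = 25L, tol = 1e-4),
    splpp = list(d = 5L)
  )
}

small_synth <- function(seed = 3L) {
  generate_synthetic(synthetic_spec(n_per_class = 40L, seed = seed))
}
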