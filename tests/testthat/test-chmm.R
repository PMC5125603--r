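test_that("emission log-density matches closed forms and the naive mixture oracle", {
  # O=1, M=1, sigma=1, frame at the mean: density 1/sqrt(2*pi)
  m <- structure(
    list(Q = 1L, M = 1L, O = 1L, pi = 1, trans = matrix(1, 1, 1),
         mix_weights = matrix(1, 1, 1), means = array(0.3, c(1, 1, 1)),
         variances = array(1, c(1, 1, 1)), variance_floor = 1e-3),
    class = "chmm"
  )
  expect_equal(emission_logdensity(m, 0.3, 1L), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)

  # M=2 equal components with equal parameters collapses to M=1
  set.seed(41)
  m1 <- random_chmm(2L, 1L, 3L)
  m2 <- m1
  m2$M <- 2L
  m2$mix_weights <- matrix(0.5, 2L, 2L)
  m2$means <- array(0, c(2L, 2L, 3L))
  m2$variances <- array(0, c(2L, 2L, 3L))
  for (comp in 1:2) {
    m2$means[, comp, ] <- m1$means[, 1L, ]
    m2$variances[, comp, ] <- m1$variances[, 1L, ]
  }
  frame <- rnorm(3)
  expect_equal(emission_logdensity(m2, frame, 1L),
               emission_logdensity(m1, frame, 1L), tolerance = 1e-10)

  # random small models vs direct linear-space summation
  for (i in 1:10) {
    mod <- random_chmm(sample(1:3, 1), sample(1:3, 1), sample(1:3, 1))
    frame <- rnorm(mod$O)
    st <- sample(mod$Q, 1)
    expect_equal(emission_logdensity(mod, frame, st),
                 log(oracle_emission_density(mod, frame, st)),
                 tolerance = 1e-9)
  }
})

test_that("forward log-likelihood equals brute-force path enumeration", {
  set.seed(42)
  for (i in 1:50) {
    Q <- sample(1:3, 1); M <- sample(1:2, 1); O <- sample(1:3, 1)
    Tn <- sample(1:6, 1)
    mod <- random_chmm(Q, M, O)
    s <- matrix(rnorm(Tn * O), Tn, O)
    expect_equal(forward_loglik(mod, s), oracle_path_loglik(mod, s),
                 tolerance = 1e-9)
  }
})

test_that("scaled and log-space forward recursions agree; degenerate shapes have closed forms", {
  set.seed(43)
  for (i in 1:20) {
    mod <- random_chmm(sample(1:4, 1), sample(1:3, 1), 2L)
    s <- matrix(rnorm(10 * 2, sd = 3), 10, 2)
    expect_equal(forward_loglik(mod, s, method = "log"),
                 forward_loglik(mod, s, method = "scaled"), tolerance = 1e-8)
  }
  # Q=1, M=1: just the sum of per-frame log densities
  mod1 <- random_chmm(1L, 1L, 2L)
  s <- matrix(rnorm(8), 4, 2)
  direct <- sum(vapply(1:4, function(t) emission_logdensity(mod1, s[t, ], 1L),
                       numeric(1)))
  expect_equal(forward_loglik(mod1, s), direct, tolerance = 1e-10)
  # T=1: log sum_i pi_i b_i(o)
  mod <- random_chmm(3L, 1L, 2L)
  o1 <- rnorm(2)
  direct1 <- log(sum(vapply(1:3, function(q)
    mod$pi[q] * oracle_emission_density(mod, o1, q), numeric(1))))
  expect_equal(forward_loglik(mod, matrix(o1, 1, 2)), direct1, tolerance = 1e-9)
  expect_error(forward_loglik(mod, matrix(0, 2, 5)), "dimension")
})

test_that("likelihood is invariant under hidden-state relabeling", {
  set.seed(44)
  mod <- random_chmm(3L, 2L, 2L)
  perm <- c(3L, 1L, 2L)
  mod_p <- mod
  mod_p$pi <- mod$pi[perm]
  mod_p$trans <- mod$trans[perm, perm]
  mod_p$mix_weights <- mod$mix_weights[perm, , drop = FALSE]
  mod_p$means <- mod$means[perm, , , drop = FALSE]
  mod_p$variances <- mod$variances[perm, , , drop = FALSE]
  s <- matrix(rnorm(12), 6, 2)
  expect_equal(forward_loglik(mod, s), forward_loglik(mod_p, s),
               tolerance = 1e-10)
})

test_that("initialization is deterministic, handles Q=M=1 and constant data", {
  set.seed(45)
  data <- lapply(1:5, function(i) matrix(rnorm(12), 4, 3))
  m1 <- init_chmm(2L, 2L, 3L, data, seed = 9L)
  m2 <- init_chmm(2L, 2L, 3L, data, seed = 9L)
  expect_identical(m1, m2)
  validate_chmm(m1)

  m <- init_chmm(1L, 1L, 3L, data, seed = 1L)
  expect_equal(m$pi, 1)
  expect_equal(m$trans, matrix(1, 1, 1))
  expect_equal(m$means[1, 1, ], colMeans(do.call(rbind, data)), tolerance = 1e-12)

  const <- list(matrix(0.5, 6, 2))
  mc <- expect_warning(init_chmm(2L, 2L, 2L, const, seed = 2L), "perturbed")
  expect_true(all(mc$variances >= mc$variance_floor))
})

test_that("Baum-Welch log-likelihood is non-decreasing and stochasticity survives every fit", {
  set.seed(46)
  for (i in 1:4) {
    truth <- random_chmm(2L, 1L, 2L)
    data <- lapply(1:20, function(j) sample_chmm(truth, 10L, seed = i * 100 + j))
    init <- init_chmm(2L, 2L, 2L, data, seed = i)
    fit <- suppressWarnings(baum_welch_fit(init, data, max_iter = 30L))
    trace <- attr(fit, "loglik_trace")
    expect_true(all(diff(trace) >= -1e-8 * pmax(abs(trace[-length(trace)]), 1)))
    validate_chmm(fit)
  }
})

test_that("Q=1 fits collapse to a trivially deterministic chain", {
  set.seed(48)
  data <- lapply(1:10, function(j) matrix(rnorm(8), 4, 2))
  fit <- baum_welch_fit(init_chmm(1L, 1L, 2L, data, seed = 1L), data,
                        max_iter = 10L)
  expect_equal(fit$trans, matrix(1, 1, 1))
  expect_equal(fit$pi, 1)
})

test_that("sampling is seed-deterministic, respects degenerate emissions and the transition law", {
  m <- structure(
    list(Q = 1L, M = 1L, O = 2L, pi = 1, trans = matrix(1, 1, 1),
         mix_weights = matrix(1, 1, 1), means = array(c(0.4, -0.2), c(1, 1, 2)),
         variances = array(1e-3, c(1, 1, 2)), variance_floor = 1e-3),
    class = "chmm"
  )
  s <- sample_chmm(m, 50L, seed = 3L)
  expect_lt(max(abs(sweep(s, 2, c(0.4, -0.2)))), 0.2)
  expect_identical(sample_chmm(m, 10L, seed = 5L), sample_chmm(m, 10L, seed = 5L))

  set.seed(49)
  chain <- random_chmm(2L, 1L, 1L)
  chain$trans <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  chain$means <- array(c(-5, 5), c(2, 1, 1))  # states identifiable from output
  chain$variances <- array(0.01, c(2, 1, 1))
  s <- sample_chmm(chain, 1e5L, seed = 8L)
  states <- ifelse(s[, 1] > 0, 2L, 1L)
  emp <- prop.table(table(head(states, -1), tail(states, -1)), margin = 1)
  expect_lt(max(abs(emp - chain$trans)), 0.01)
})

test_that("bank classification picks the generating model, breaks ties by smallest label, matches the enumeration oracle", {
  set.seed(50)
  truth <- random_chmm(2L, 1L, 2L)
  shifted <- truth
  shifted$means <- truth$means + 10 * sqrt(max(truth$variances))
  bank <- chmm_bank(list(`2` = shifted, `1` = truth))
  hits <- 0L
  for (j in 1:10) {
    s <- sample_chmm(truth, 20L, seed = 600 + j)
    res <- classify_chmm(bank, s)
    if (res$label == "1") hits <- hits + 1L
    # argmax agrees with brute-force path-sum likelihoods
    o1 <- oracle_path_loglik(truth, s[1:4, , drop = FALSE])
    o2 <- oracle_path_loglik(shifted, s[1:4, , drop = FALSE])
    r4 <- classify_chmm(bank, s[1:4, , drop = FALSE])
    expect_identical(r4$label, if (o1 >= o2) "1" else "2")
  }
  expect_identical(hits, 10L)

  tie_bank <- chmm_bank(list(`5` = truth, `2` = truth))
  res <- classify_chmm(tie_bank, sample_chmm(truth, 5L, seed = 1L))
  expect_identical(res$label, "2")
  expect_identical(sort(names(res$logliks)), c("2", "5"))
})

test_that("JSON serialization round-trips a model at printed precision", {
  set.seed(51)
  mod <- random_chmm(3L, 2L, 4L)
  mod2 <- chmm_from_json(chmm_to_json(mod))
  expect_equal(mod2$pi, mod$pi, tolerance = 1e-12)
  expect_equal(mod2$trans, mod$trans, tolerance = 1e-12)
  expect_equal(mod2$mix_weights, mod$mix_weights, tolerance = 1e-12)
  expect_equal(mod2$means, mod$means, tolerance = 1e-12)
  expect_equal(mod2$variances, mod$variances, tolerance = 1e-12)
  s <- matrix(rnorm(8), 2, 4)
  expect_equal(forward_loglik(mod2, s), forward_loglik(mod, s), tolerance = 1e-12)
})
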