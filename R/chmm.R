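# Continuous hidden Markov models with per-state diagonal Gaussian-mixture
# emissions: construction, log-space/scaled forward likelihood, Baum-Welch
# EM over sequence batches, sampling, and max-likelihood bank classification.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

new_chmm <- function(Q, M, O, pi, trans, mix_weights, means, variances,
                     variance_floor) {
  model <- structure(
    list(Q = as.integer(Q), M = as.integer(M), O = as.integer(O),
         pi = pi, trans = trans, mix_weights = mix_weights,
         means = means, variances = variances,
         variance_floor = variance_floor),
    class = "chmm"
  )
  validate_chmm(model)
  model
}

#' Validate a continuous HMM's stochasticity invariants
#'
#' Checks that the initial distribution, every transition row and every
#' mixture-weight row sum to one (within 1e-9), and that all variances sit
#' at or above the variance floor.
#'
#' @param model a \code{chmm}.
#' @return \code{model}, invisibly; errors on violation.
#' @export
validate_chmm <- function(model) {
  stopifnot(inherits(model, "chmm"))
  with(model, {
    stopifnot(length(pi) == Q, nrow(trans) == Q, ncol(trans) == Q,
              nrow(mix_weights) == Q, ncol(mix_weights) == M,
              all(dim(means) == c(Q, M, O)),
              all(dim(variances) == c(Q, M, O)))
    if (abs(sum(pi) - 1) > 1e-9) stop("pi does not sum to 1")
    if (any(abs(rowSums(trans) - 1) > 1e-9)) stop("trans rows must sum to 1")
    if (any(abs(rowSums(mix_weights) - 1) > 1e-9)) {
      stop("mix_weights rows must sum to 1")
    }
    if (any(variances < variance_floor - 1e-12)) {
      stop("variances below the variance floor")
    }
  })
  invisible(model)
}

#' Initialize a Gaussian-mixture continuous HMM from data
#'
#' Uniform initial and transition distributions; component means from a
#' seeded k-means over all pooled frames (k = Q*M); variances set to the
#' per-dimension pooled variance, floored. When fewer pooled frames than
#' components are available (or k-means degenerates), means fall back to
#' small seeded perturbations of the global frame mean, with a warning.
#'
#' @param Q hidden states. @param M mixture components per state.
#' @param O observation (frame) dimension.
#' @param data list of T x O frame matrices (a sequence batch).
#' @param seed integer seed for the k-means initialization.
#' @param variance_floor lower bound applied to every variance
#'   (default 1e-3, calibrated for \eqn{[-1,1]}-normalized features).
#' @return a \code{chmm}.
#' @export
init_chmm <- function(Q, M, O, data, seed, variance_floor = 1e-3) {
  stopifnot(Q >= 1L, M >= 1L, O >= 1L, length(data) >= 1L)
  frames <- do.call(rbind, data)
  if (ncol(frames) != O) stop(sprintf("frames have dim %d, expected O = %d", ncol(frames), O))
  k <- Q * M
  pooled_var <- pmax(apply(frames, 2L, stats::var), variance_floor)
  pooled_var[is.na(pooled_var)] <- variance_floor
  centers <- NULL
  if (nrow(frames) >= k && nrow(unique(frames)) >= k) {
    centers <- tryCatch({
      set.seed(as.integer(seed))
      stats::kmeans(frames, centers = k, nstart = 3L, iter.max = 50L)$centers
    }, error = function(e) NULL)
  }
  if (is.null(centers)) {
    warning("fewer distinct frames than Q*M components; ",
            "initializing means as perturbed global mean")
    set.seed(as.integer(seed))
    gm <- colMeans(frames)
    centers <- matrix(rep(gm, each = k), k, O) +
      matrix(stats::rnorm(k * O, sd = sqrt(variance_floor)), k, O)
  }
  means <- array(0, c(Q, M, O))
  variances <- array(rep(pooled_var, each = Q * M), c(Q, M, O))
  idx <- 1L
  for (q in seq_len(Q)) for (m in seq_len(M)) {
    means[q, m, ] <- centers[idx, ]
    idx <- idx + 1L
  }
  new_chmm(
    Q, M, O,
    pi = rep(1 / Q, Q),
    trans = matrix(1 / Q, Q, Q),
    mix_weights = matrix(1 / M, Q, M),
    means = means,
    variances = pmax(variances, variance_floor),
    variance_floor = variance_floor
  )
}

# Per-frame, per-state, per-component joint log densities for a sequence:
# lcomp[t, q, m] = log(c_qm) + sum_o log N(frame[t,o]; mu, var).
# Returns list(lcomp = T x Q x M array, logB = T x Q state log densities).
chmm_logdensities <- function(model, sequence) {
  Tn <- nrow(sequence); Q <- model$Q; M <- model$M
  lcomp <- array(0, c(Tn, Q, M))
  for (q in seq_len(Q)) {
    for (m in seq_len(M)) {
      mu <- model$means[q, m, ]
      v <- model$variances[q, m, ]
      dev <- sweep(sequence, 2L, mu)
      lcomp[, q, m] <- log(model$mix_weights[q, m]) -
        0.5 * (sum(log(2 * pi * v)) + (dev * dev) %*% (1 / v))
    }
  }
  logB <- matrix(0, Tn, Q)
  for (q in seq_len(Q)) {
    if (M == 1L) {
      logB[, q] <- lcomp[, q, 1L]
    } else {
      lm <- matrix(lcomp[, q, ], nrow = Tn, ncol = M)
      mx <- apply(lm, 1L, max)
      logB[, q] <- mx + log(rowSums(exp(lm - mx)))
    }
  }
  list(lcomp = lcomp, logB = logB)
}

#' Log emission density of one frame under one hidden state
#'
#' \eqn{\log \sum_m c_m \prod_o N(o; \mu, \sigma^2)}, evaluated in
#' log-space with log-sum-exp.
#'
#' @param model a \code{chmm}. @param frame numeric O-vector.
#' @param state hidden state index in 1..Q.
#' @return scalar log density (always finite for floored variances).
#' @export
emission_logdensity <- function(model, frame, state) {
  stopifnot(inherits(model, "chmm"), state >= 1L, state <= model$Q,
            length(frame) == model$O)
  ld <- chmm_logdensities(model, matrix(frame, nrow = 1L))
  ld$logB[1L, state]
}

#' Sequence log-likelihood via the forward algorithm
#'
#' Computes \eqn{\log P(O \mid \lambda)} exactly. The reference path is a
#' pure log-space recursion with log-sum-exp; \code{method = "scaled"}
#' runs the classic normalized-alpha recursion instead (the two agree to
#' ~1e-8 and are cross-checked in the test suite).
#'
#' @param model a \code{chmm}.
#' @param sequence T x O frame matrix (a numeric O-vector is accepted as a
#'   single frame).
#' @param method \code{"log"} (default) or \code{"scaled"}.
#' @return scalar log-likelihood.
#' @export
forward_loglik <- function(model, sequence, method = c("log", "scaled")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "chmm"))
  if (is.vector(sequence)) sequence <- matrix(sequence, nrow = 1L)
  if (nrow(sequence) < 1L) stop("empty sequence")
  if (ncol(sequence) != model$O) {
    stop(sprintf("frame dimension %d does not match O = %d",
                 ncol(sequence), model$O))
  }
  logB <- chmm_logdensities(model, sequence)$logB
  if (method == "log") {
    forward_log(model, logB)$loglik
  } else {
    forward_scaled(model, logB)
  }
}

# log-space forward pass; returns log-alpha matrix and total log-likelihood
forward_log <- function(model, logB) {
  Tn <- nrow(logB); Q <- model$Q
  ltrans <- log(model$trans)
  la <- matrix(-Inf, Tn, Q)
  la[1L, ] <- log(model$pi) + logB[1L, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      for (j in seq_len(Q)) {
        la[t, j] <- logsumexp(la[t - 1L, ] + ltrans[, j]) + logB[t, j]
      }
    }
  }
  list(la = la, loglik = logsumexp(la[Tn, ]))
}

# scaled (normalized-alpha) forward pass; returns the log-likelihood
forward_scaled <- function(model, logB) {
  Tn <- nrow(logB); Q <- model$Q
  # per-row max shift keeps exp() in range even for extreme frames
  shift <- apply(logB, 1L, max)
  Bm <- exp(logB - shift)
  alpha <- model$pi * Bm[1L, ]
  c1 <- sum(alpha)
  if (c1 == 0) return(-Inf)
  alpha <- alpha / c1
  ll <- log(c1) + shift[1L]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      alpha <- as.vector(crossprod(model$trans, alpha)) * Bm[t, ]
      ct <- sum(alpha)
      if (ct == 0) return(-Inf)
      alpha <- alpha / ct
      ll <- ll + log(ct) + shift[t]
    }
  }
  ll
}

# log-space backward pass
backward_log <- function(model, logB) {
  Tn <- nrow(logB); Q <- model$Q
  ltrans <- log(model$trans)
  lb <- matrix(0, Tn, Q)
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      for (i in seq_len(Q)) {
        lb[t, i] <- logsumexp(ltrans[i, ] + logB[t + 1L, ] + lb[t + 1L, ])
      }
    }
  }
  lb
}

#' Fit a continuous HMM by Baum-Welch expectation-maximization
#'
#' Standard multi-sequence EM for Gaussian-mixture emissions with diagonal
#' covariance. The total log-likelihood is non-decreasing across
#' iterations (up to ~1e-8 numerical slack); iteration stops when the
#' relative improvement drops below \code{tol} or after \code{max_iter}
#' iterations. Variances are re-floored after every M-step. A mixture
#' component that collects (numerically) no responsibility is re-seeded
#' from a pooled frame, with a warning.
#'
#' @param model initial \code{chmm} (see \code{\link{init_chmm}}).
#' @param data list of T x O frame matrices.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative log-likelihood improvement threshold (default 1e-5).
#' @return the fitted \code{chmm}, with the per-iteration log-likelihood
#'   trace in \code{attr(, "loglik_trace")}.
#' @export
baum_welch_fit <- function(model, data, max_iter = 100L, tol = 1e-5) {
  stopifnot(inherits(model, "chmm"), length(data) >= 1L)
  data <- lapply(data, function(s) if (is.vector(s)) matrix(s, nrow = 1L) else s)
  Q <- model$Q; M <- model$M; O <- model$O
  frames <- do.call(rbind, data)
  pooled_var <- pmax(apply(frames, 2L, stats::var), model$variance_floor)
  pooled_var[is.na(pooled_var)] <- model$variance_floor
  trace <- numeric(0)
  warned_empty <- FALSE
  for (iter in seq_len(max_iter)) {
    pi_acc <- numeric(Q)
    xi_acc <- matrix(0, Q, Q)
    wsum <- matrix(0, Q, M)                 # total component responsibility
    msum <- array(0, c(Q, M, O))            # responsibility-weighted frames
    ssum <- array(0, c(Q, M, O))            # responsibility-weighted squares
    ll_total <- 0
    for (s in data) {
      ld <- chmm_logdensities(model, s)
      fwd <- forward_log(model, ld$logB)
      lb <- backward_log(model, ld$logB)
      ll <- fwd$loglik
      ll_total <- ll_total + ll
      lgamma_ <- fwd$la + lb - ll
      gamma_ <- exp(lgamma_)
      pi_acc <- pi_acc + gamma_[1L, ]
      Tn <- nrow(s)
      if (Tn > 1L) {
        ltrans <- log(model$trans)
        for (t in seq_len(Tn - 1L)) {
          lxi <- outer(fwd$la[t, ], ld$logB[t + 1L, ] + lb[t + 1L, ], "+") +
            ltrans - ll
          xi_acc <- xi_acc + exp(lxi)
        }
      }
      for (q in seq_len(Q)) {
        # split state responsibility across mixture components
        lrm <- matrix(ld$lcomp[, q, ], nrow = Tn, ncol = M)
        resp <- gamma_[, q] * exp(lrm - ld$logB[, q])
        for (m in seq_len(M)) {
          r <- resp[, m]
          wsum[q, m] <- wsum[q, m] + sum(r)
          msum[q, m, ] <- msum[q, m, ] + colSums(r * s)
          ssum[q, m, ] <- ssum[q, m, ] + colSums(r * s * s)
        }
      }
    }
    trace <- c(trace, ll_total)
    # M-step
    model$pi <- pi_acc / sum(pi_acc)
    rs <- rowSums(xi_acc)
    trans <- xi_acc
    for (q in seq_len(Q)) {
      trans[q, ] <- if (rs[q] > 0) xi_acc[q, ] / rs[q] else rep(1 / Q, Q)
    }
    # single-frame-only batches never visit a transition: keep the chain
    if (all(rs == 0)) trans <- model$trans
    model$trans <- trans
    for (q in seq_len(Q)) {
      for (m in seq_len(M)) {
        if (wsum[q, m] > 1e-10) {
          mu <- msum[q, m, ] / wsum[q, m]
          v <- ssum[q, m, ] / wsum[q, m] - mu * mu
          model$means[q, m, ] <- mu
          model$variances[q, m, ] <- pmax(v, model$variance_floor)
        } else {
          if (!warned_empty) {
            warning("empty mixture component re-seeded from a pooled frame")
            warned_empty <- TRUE
          }
          pick <- ((iter * 31L + q * 7L + m) %% nrow(frames)) + 1L
          model$means[q, m, ] <- frames[pick, ]
          model$variances[q, m, ] <- pooled_var
          wsum[q, m] <- 1e-8
        }
      }
    }
    mw <- wsum / rowSums(wsum)
    model$mix_weights <- mw
    if (iter >= 2L) {
      prev <- trace[iter - 1L]
      if ((trace[iter] - prev) <= tol * abs(prev)) break
    }
  }
  validate_chmm(model)
  attr(model, "loglik_trace") <- trace
  model
}

#' Sample a frame sequence from a continuous HMM
#'
#' States are drawn from the chain (initial distribution, then transition
#' rows); each frame from the state's Gaussian mixture. Deterministic for
#' a given seed.
#'
#' @param model a \code{chmm}. @param T_len sequence length (frames).
#' @param seed integer seed.
#' @return T x O numeric frame matrix.
#' @export
sample_chmm <- function(model, T_len, seed) {
  stopifnot(inherits(model, "chmm"), T_len >= 1L)
  set.seed(as.integer(seed))
  Q <- model$Q; M <- model$M; O <- model$O
  out <- matrix(0, T_len, O)
  state <- sample.int(Q, 1L, prob = model$pi)
  for (t in seq_len(T_len)) {
    if (t > 1L) state <- sample.int(Q, 1L, prob = model$trans[state, ])
    comp <- sample.int(M, 1L, prob = model$mix_weights[state, ])
    out[t, ] <- stats::rnorm(O, mean = model$means[state, comp, ],
                             sd = sqrt(model$variances[state, comp, ]))
  }
  out
}

#' Build a model bank
#'
#' One generative model per class label; classification picks the label
#' whose model scores the observation highest.
#'
#' @param models named list of \code{chmm} objects (names are class
#'   labels); all models must share the frame dimension O.
#' @return a \code{chmm_bank}.
#' @export
chmm_bank <- function(models) {
  stopifnot(is.list(models), length(models) >= 1L,
            !is.null(names(models)), all(nzchar(names(models))))
  Os <- vapply(models, function(m) m$O, integer(1L))
  if (length(unique(Os)) != 1L) stop("all bank models must share O")
  structure(list(models = models), class = "chmm_bank")
}

#' Max-likelihood classification against a model bank
#'
#' Scores the sequence under every model with the forward algorithm and
#' returns the label of the highest log-likelihood; ties are broken by the
#' smallest label code (numeric order when all labels are numeric,
#' lexicographic otherwise).
#'
#' @param bank a \code{chmm_bank}. @param sequence T x O frame matrix.
#' @return list with \code{label} (character) and \code{logliks} (named
#'   numeric vector over all bank labels).
#' @export
classify_chmm <- function(bank, sequence) {
  stopifnot(inherits(bank, "chmm_bank"))
  lls <- vapply(bank$models, forward_loglik, numeric(1L), sequence = sequence)
  if (all(!is.finite(lls))) {
    stop("sequence is unscorable: all bank log-likelihoods are -Inf")
  }
  labels <- names(bank$models)
  ord <- if (all(!is.na(suppressWarnings(as.numeric(labels))))) {
    order(as.numeric(labels))
  } else {
    order(labels)
  }
  lls_ord <- lls[ord]
  best <- names(lls_ord)[which.max(lls_ord)]  # which.max takes the first tie
  list(label = best, logliks = lls)
}

#' Serialize a continuous HMM to JSON text
#' @param model a \code{chmm}.
#' @return a JSON string (full double precision).
#' @export
chmm_to_json <- function(model) {
  stopifnot(inherits(model, "chmm"))
  payload <- list(
    Q = model$Q, M = model$M, O = model$O,
    pi = model$pi,
    trans = model$trans,
    mix_weights = model$mix_weights,
    means = as.vector(model$means),
    variances = as.vector(model$variances),
    variance_floor = model$variance_floor
  )
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
}

#' Deserialize a continuous HMM from JSON text
#' @param json a string produced by \code{\link{chmm_to_json}}.
#' @return a \code{chmm}.
#' @export
chmm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  Q <- x$Q; M <- x$M; O <- x$O
  new_chmm(
    Q, M, O,
    pi = as.numeric(x$pi),
    trans = matrix(as.numeric(x$trans), Q, Q),
    mix_weights = matrix(as.numeric(x$mix_weights), Q, M),
    means = array(as.numeric(x$means), c(Q, M, O)),
    variances = array(as.numeric(x$variances), c(Q, M, O)),
    variance_floor = x$variance_floor
  )
}

#' @export
print.chmm <- function(x, ...) {
  cat(sprintf("chmm: Q=%d states, M=%d mixtures, O=%d dims, floor=%g\n",
              x$Q, x$M, x$O, x$variance_floor))
  invisible(x)
}
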