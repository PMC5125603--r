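# Synthetic feature-window generator emulating the UCI-HAR layout:
# six hierarchically structured activity classes, Acc/Gyro-named channels,
# [-1,1] normalization and a stratified 70/30 split. Each window is sampled
# from a class-specific two-state Gaussian CHMM over short frames and
# flattened to a feature vector, so the data carries the temporal and
# group structure every pipeline stage relies on.

#' Specification of a synthetic HAR dataset
#'
#' The six class-conditional generators are arranged so that each pipeline
#' stage is non-trivially useful: moving \{1,2,3\} and stationary \{4,5,6\}
#' groups are widely separated on accelerometer channels; classes 2 and 3
#' (up/downstairs) have identical accelerometer marginals and differ only
#' on gyroscope channels; classes 4 and 5 (sitting/standing) differ along
#' a low-dimensional direction; class 6 (laying) is far from both; 40% of
#' the channels are pure noise with no class information.
#'
#' @param n_per_class windows per class (default 100).
#' @param p feature count; must be a multiple of \code{frame_channels}
#'   (default 60: six 10-channel frames).
#' @param acc_fraction fraction of channels per frame carrying "Acc" names
#'   (default 0.5; the rest are "Gyro"-named).
#' @param separation scalar multiplying every class-mean offset
#'   (default 1; 0 yields indistinguishable classes).
#' @param noise_sd per-channel emission standard deviation (default 0.15).
#' @param seed integer seed. @param train_fraction default 0.70.
#' @param frame_channels channels per generator frame (default 10).
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_per_class = 100L, p = 60L, acc_fraction = 0.5,
                           separation = 1, noise_sd = 0.15, seed = 0L,
                           train_fraction = 0.7, frame_channels = 10L) {
  if (n_per_class < 4L) stop("n_per_class must be at least 4")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  if (p %% frame_channels != 0L) {
    stop(sprintf("p = %d must be a multiple of frame_channels = %d",
                 p, frame_channels))
  }
  if (acc_fraction < 0 || acc_fraction > 1) stop("acc_fraction must be in [0,1]")
  structure(
    list(n_per_class = as.integer(n_per_class), p = as.integer(p),
         acc_fraction = acc_fraction, separation = separation,
         noise_sd = noise_sd, seed = as.integer(seed),
         train_fraction = train_fraction,
         frame_channels = as.integer(frame_channels)),
    class = "synthetic_spec"
  )
}

# Per-frame channel layout: the first round(acc_fraction * C) channels are
# Acc-named, the rest Gyro-named; within each block the last 40% of
# channels carry no class signal (pure noise channels).
synthetic_layout <- function(spec) {
  C <- spec$frame_channels
  n_acc <- round(spec$acc_fraction * C)
  acc_idx <- seq_len(n_acc)
  gyro_idx <- setdiff(seq_len(C), acc_idx)
  split_inf <- function(idx) {
    n_noise <- round(0.4 * length(idx))
    list(inf = idx[seq_len(length(idx) - n_noise)],
         noise = if (n_noise > 0) idx[(length(idx) - n_noise + 1):length(idx)] else integer(0))
  }
  acc <- split_inf(acc_idx)
  gyro <- split_inf(gyro_idx)
  list(C = C, acc = acc_idx, gyro = gyro_idx,
       acc_inf = acc$inf, acc_noise = acc$noise,
       gyro_inf = gyro$inf, gyro_noise = gyro$noise)
}

# Build the six class-conditional 2-state CHMMs (M = 1 mixture) over one
# frame of C channels.
synthetic_class_models <- function(spec) {
  lay <- synthetic_layout(spec)
  s <- spec$separation
  C <- lay$C
  base <- function() numeric(C)
  mu <- list()
  for (k in 1:6) mu[[k]] <- base()
  # moving vs stationary: wide split on Acc-informative channels
  for (k in 1:3) mu[[k]][lay$acc_inf] <- 0.6 * s
  for (k in 4:6) mu[[k]][lay$acc_inf] <- -0.6 * s
  # walking distinct from up/down on Acc; classes 2 and 3 identical on Acc
  mu[[1]][lay$acc_inf] <- 0.95 * s
  mu[[2]][lay$acc_inf] <- 0.45 * s
  mu[[3]][lay$acc_inf] <- 0.45 * s
  # up vs down: all structure on Gyro-informative channels
  mu[[2]][lay$gyro_inf] <- 0.5 * s
  mu[[3]][lay$gyro_inf] <- -0.5 * s
  # laying far from sitting/standing on Acc
  mu[[6]][lay$acc_inf] <- -0.95 * s
  mu[[4]][lay$acc_inf] <- -0.45 * s
  mu[[5]][lay$acc_inf] <- -0.45 * s
  # sitting vs standing: low-dimensional direction on two Gyro channels
  sub <- lay$gyro_inf[seq_len(min(2L, length(lay$gyro_inf)))]
  mu[[4]][sub] <- mu[[4]][sub] + 0.3 * s
  mu[[5]][sub] <- mu[[5]][sub] - 0.3 * s
  inf_all <- c(lay$acc_inf, lay$gyro_inf)
  lapply(1:6, function(k) {
    means <- array(0, c(2L, 1L, C))
    offset <- numeric(C)
    offset[inf_all] <- 0.12 * s  # temporal state contrast on informative channels
    means[1L, 1L, ] <- mu[[k]] - offset
    means[2L, 1L, ] <- mu[[k]] + offset
    variances <- array(spec$noise_sd^2, c(2L, 1L, C))
    new_chmm(
      Q = 2L, M = 1L, O = C,
      pi = c(0.5, 0.5),
      trans = matrix(c(0.8, 0.2, 0.2, 0.8), 2L, 2L, byrow = TRUE),
      mix_weights = matrix(1, 2L, 1L),
      means = means, variances = pmax(variances, 1e-3),
      variance_floor = 1e-3
    )
  })
}

#' Generate a synthetic train/test dataset pair
#'
#' Draws \code{6 * n_per_class} windows (each a flattened frame sequence
#' from its class's generative CHMM), assigns UCI-style channel names
#' (\code{tBodyAcc-f<j>} / \code{tBodyGyro-f<j>}), splits stratified by
#' class at \code{train_fraction}, and min-max normalizes every column to
#' \eqn{[-1,1]} using training-split statistics (test values clipped).
#' Deterministic for a given spec.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{train} and \code{test} \code{har_dataset}s.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  models <- synthetic_class_models(spec)
  lay <- synthetic_layout(spec)
  T_gen <- spec$p %/% spec$frame_channels
  n <- spec$n_per_class
  X <- matrix(0, 6L * n, spec$p)
  y <- integer(6L * n)
  row <- 1L
  for (k in 1:6) {
    for (i in seq_len(n)) {
      # one sub-seed per window, derived deterministically from the spec seed
      w_seed <- (spec$seed * 7919L + k * 1009L + i * 13L) %% .Machine$integer.max
      frames <- sample_chmm(models[[k]], T_gen, seed = w_seed)
      X[row, ] <- as.vector(t(frames))  # frame-major flattening
      y[row] <- k
      row <- row + 1L
    }
  }
  names_per_col <- vapply(seq_len(spec$p), function(j) {
    c_in_frame <- (j - 1L) %% spec$frame_channels + 1L
    kind <- if (c_in_frame %in% lay$acc) "tBodyAcc" else "tBodyGyro"
    sprintf("%s-f%d", kind, j)
  }, character(1L))
  # stratified split
  set.seed(spec$seed)
  n_train <- round(spec$train_fraction * n)
  train_rows <- unlist(lapply(1:6, function(k) {
    rows_k <- which(y == k)
    sample(rows_k, n_train)
  }))
  test_rows <- setdiff(seq_len(6L * n), train_rows)
  # per-column min-max normalization to [-1,1] fitted on the training split
  lo <- apply(X[train_rows, , drop = FALSE], 2L, min)
  hi <- apply(X[train_rows, , drop = FALSE], 2L, max)
  span <- pmax(hi - lo, 1e-12)
  normalize <- function(M) {
    Z <- sweep(sweep(M, 2L, lo), 2L, span, "/") * 2 - 1
    pmin(pmax(Z, -1), 1)
  }
  list(
    train = har_dataset(normalize(X[train_rows, , drop = FALSE]),
                        y[train_rows], names_per_col, split = "train"),
    test = har_dataset(normalize(X[test_rows, , drop = FALSE]),
                       y[test_rows], names_per_col, split = "test")
  )
}

#' Human-readable description of a synthetic spec
#'
#' One \code{key: value} line per parameter; parseable back into an
#' equivalent spec with \code{\link{parse_synthetic_description}}.
#'
#' @param spec a \code{synthetic_spec}.
#' @return character vector of lines.
#' @export
describe_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  c(
    "synthetic HAR feature-window generator",
    sprintf("n_per_class: %d", spec$n_per_class),
    sprintf("p: %d", spec$p),
    sprintf("frame_channels: %d", spec$frame_channels),
    sprintf("acc_fraction: %.17g", spec$acc_fraction),
    sprintf("separation: %.17g", spec$separation),
    sprintf("noise_sd: %.17g", spec$noise_sd),
    sprintf("train_fraction: %.17g", spec$train_fraction),
    sprintf("seed: %d", spec$seed)
  )
}

#' Parse a description block back into a synthetic spec
#' @param lines character vector as produced by
#'   \code{\link{describe_synthetic}}.
#' @return a \code{synthetic_spec}.
#' @export
parse_synthetic_description <- function(lines) {
  kv <- lines[grepl(":", lines, fixed = TRUE)]
  parts <- strsplit(kv, ":[ \t]*")
  vals <- stats::setNames(
    vapply(parts, function(x) paste(x[-1L], collapse = ":"), character(1L)),
    vapply(parts, `[[`, character(1L), 1L)
  )
  synthetic_spec(
    n_per_class = as.integer(vals[["n_per_class"]]),
    p = as.integer(vals[["p"]]),
    frame_channels = as.integer(vals[["frame_channels"]]),
    acc_fraction = as.numeric(vals[["acc_fraction"]]),
    separation = as.numeric(vals[["separation"]]),
    noise_sd = as.numeric(vals[["noise_sd"]]),
    train_fraction = as.numeric(vals[["train_fraction"]]),
    seed = as.integer(vals[["seed"]])
  )
}

#' Write a synthetic dataset pair as UCI-dialect files
#'
#' Emits \code{X_train.txt}, \code{y_train.txt}, \code{X_test.txt},
#' \code{y_test.txt}, \code{features.txt} and \code{provenance.txt}
#' (the spec description) under \code{dir}.
#'
#' @param spec a \code{synthetic_spec}. @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_files <- function(spec, dir) {
  data <- generate_synthetic(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(data$train$X, file.path(dir, "X_train.txt"))
  write_labels(data$train$y, file.path(dir, "y_train.txt"))
  write_feature_matrix(data$test$X, file.path(dir, "X_test.txt"))
  write_labels(data$test$y, file.path(dir, "y_test.txt"))
  write_feature_names(data$train$feature_names, file.path(dir, "features.txt"))
  writeLines(describe_synthetic(spec), file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  writeLines(describe_synthetic(x))
  invisible(x)
}
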