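#' Random-forest variable-importance scores with above-mean selection
#'
#' Fits a seeded random forest to the labeled feature windows and scores
#' every feature, then applies the above-mean retention rule: a feature is
#' kept whenever its score is greater than or equal to the arithmetic mean
#' of all scores (ties at the mean are retained).
#'
#' @param dataset a \code{har_dataset}.
#' @param ntree number of trees (default 500).
#' @param mtry variables tried at each split; default
#'   \code{floor(sqrt(p))} where p is the feature count.
#' @param seed integer seed; required so the run-dependent scores are
#'   reproducible.
#' @param repeats number of independent forests whose scores are averaged
#'   (default 1); repeat r uses seed \code{seed + r - 1}.
#' @param importance \code{"impurity"} (mean decrease in Gini, default) or
#'   \code{"permutation"}; permutation scores are clamped at zero.
#' @return an object of class \code{rfim_result} with elements
#'   \code{scores} (named, length p, nonnegative), \code{mean_score},
#'   \code{selected} (sorted indices of retained features) and
#'   \code{rf_params}.
#' @export
compute_importance <- function(dataset, ntree = 500L, mtry = NULL, seed,
                               repeats = 1L,
                               importance = c("impurity", "permutation")) {
  stopifnot(inherits(dataset, "har_dataset"))
  importance <- match.arg(importance)
  p <- ncol(dataset$X)
  n <- nrow(dataset$X)
  if (p < 1L) stop("dataset has no features; importance undefined")
  if (n < 2L) stop("need at least two windows to fit a forest")
  if (length(unique(dataset$y)) < 2L) {
    stop("all labels identical; variable importance is undefined")
  }
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  df <- as.data.frame(dataset$X)
  colnames(df) <- sprintf("f%d", seq_len(p))
  df$.label <- factor(dataset$y)
  acc <- numeric(p)
  for (r in seq_len(repeats)) {
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = df,
      num.trees = ntree, mtry = mtry, importance = importance,
      seed = as.integer(seed) + r - 1L, num.threads = 1L,
      write.forest = FALSE
    )
    acc <- acc + as.numeric(fit$variable.importance)
  }
  scores <- pmax(acc / repeats, 0)
  names(scores) <- dataset$feature_names
  res <- structure(
    list(
      scores = scores,
      mean_score = mean(scores),
      selected = integer(0),
      rf_params = list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                       seed = as.integer(seed), repeats = as.integer(repeats),
                       importance = importance)
    ),
    class = "rfim_result"
  )
  res$selected <- select_above_mean(res)
  res
}

#' Above-mean selection rule
#'
#' Pure arithmetic over stored scores: returns the sorted indices
#' \code{i} with \code{scores[i] >= mean(scores)}. Never touches the data.
#'
#' @param result an \code{rfim_result} (or any list with a numeric
#'   \code{scores} element).
#' @return sorted integer index vector; nonempty whenever p >= 1.
#' @export
select_above_mean <- function(result) {
  scores <- result$scores
  stopifnot(is.numeric(scores), length(scores) >= 1L)
  sort(which(scores >= mean(scores)))
}

#' Restrict a dataset to selected feature columns
#'
#' @param dataset a \code{har_dataset}.
#' @param indices integer column indices (1-based), kept in the given order.
#' @return a \code{har_dataset} with the selected columns and matching
#'   feature names; row count unchanged.
#' @export
apply_selection <- function(dataset, indices) {
  stopifnot(inherits(dataset, "har_dataset"))
  indices <- as.integer(indices)
  p <- ncol(dataset$X)
  if (length(indices) == 0L) stop("empty selection")
  if (any(indices < 1L | indices > p)) {
    stop(sprintf("selection index out of range 1..%d", p))
  }
  har_dataset(dataset$X[, indices, drop = FALSE], dataset$y,
              dataset$feature_names[indices], split = dataset$split)
}

#' @export
print.rfim_result <- function(x, ...) {
  cat(sprintf(
    "rfim_result: %d features, mean score %.4g, %d selected (ntree=%d, mtry=%d, seed=%d)\n",
    length(x$scores), x$mean_score, length(x$selected),
    x$rf_params$ntree, x$rf_params$mtry, x$rf_params$seed
  ))
  invisible(x)
}

#' Write an importance table as TSV
#'
#' Columns: feature name, score, selected flag.
#' @param result an \code{rfim_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_importance_tsv <- function(result, path) {
  df <- data.frame(
    feature = names(result$scores),
    score = as.numeric(result$scores),
    selected = seq_along(result$scores) %in% result$selected
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
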