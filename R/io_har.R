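#' Read a whitespace-delimited feature matrix
#'
#' Parses a plain-text numeric matrix in the UCI-HAR \code{X_train.txt}
#' dialect: one window per line, features separated by arbitrary runs of
#' spaces and/or tabs, scientific notation allowed.
#'
#' @param path path to an existing text file.
#' @return a numeric matrix, one row per input line, row order preserved.
#' @export
read_feature_matrix <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty feature matrix file: ", path)
  }
  tokens <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(tokens)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "ragged feature matrix in %s: row %d has %d tokens, expected %d",
      path, bad, widths[bad], widths[1L]
    ))
  }
  flat <- unlist(tokens, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    row <- (bad - 1L) %/% widths[1L] + 1L
    stop(sprintf(
      "non-numeric token '%s' in %s at row %d", flat[bad], path, row
    ))
  }
  matrix(vals, nrow = length(lines), ncol = widths[1L], byrow = TRUE)
}

#' Write a feature matrix in the UCI-HAR text dialect
#'
#' Values are formatted with \code{fmt} (default \code{"\%.6g"}) and joined
#' with single spaces, so a write/read cycle is stable at the precision the
#' data carries.
#'
#' @param x numeric matrix.
#' @param path output file path.
#' @param fmt \code{sprintf} format for each value.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(x, path, fmt = "%.6g") {
  stopifnot(is.matrix(x), is.numeric(x))
  lines <- apply(x, 1L, function(row) paste(sprintf(fmt, row), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an activity label file
#'
#' One integer label per line (\code{y_train.txt} dialect).
#'
#' @param path path to the label file.
#' @param strict if \code{TRUE}, labels outside \code{1:6} are rejected.
#' @return integer vector of labels.
#' @export
read_labels <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || any(vals != floor(vals))) {
    bad <- which(is.na(vals) | vals != floor(vals))[1L]
    stop(sprintf("non-integer label '%s' at line %d of %s", lines[bad], bad, path))
  }
  vals <- as.integer(vals)
  if (strict && any(vals < 1L | vals > 6L)) {
    bad <- which(vals < 1L | vals > 6L)[1L]
    stop(sprintf(
      "label %d at line %d of %s outside the activity code range 1..6",
      vals[bad], bad, path
    ))
  }
  vals
}

#' Write an activity label file
#' @param y integer label vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(y, path) {
  writeLines(as.character(as.integer(y)), path)
  invisible(path)
}

#' Read a feature-name list
#'
#' One name per line (\code{features.txt} dialect). Lines of the form
#' \code{"<index> <name>"} (the released UCI-HAR format) are accepted; the
#' index is dropped.
#'
#' @param path path to the name list.
#' @return character vector of feature names.
#' @export
read_feature_names <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), function(tok) {
    if (length(tok) >= 2L && grepl("^[0-9]+$", tok[1L])) {
      paste(tok[-1L], collapse = " ")
    } else {
      paste(tok, collapse = " ")
    }
  }, character(1L))
}

#' Write a feature-name list (indexed UCI dialect)
#' @param names character vector of feature names.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_names <- function(names, path) {
  writeLines(sprintf("%d %s", seq_along(names), names), path)
  invisible(path)
}

#' Assemble a labeled feature-window dataset
#'
#' Bundles a feature matrix, activity labels (codes 1..6: Walking=1,
#' Upstairs=2, Downstairs=3, Sitting=4, Standing=5, Laying=6) and feature
#' names into a \code{har_dataset}, validating that all dimensions agree.
#' The \code{normalized} flag is set by scanning whether every entry lies in
#' \eqn{[-1, 1]}.
#'
#' @param X numeric matrix, N windows by p features.
#' @param y integer labels, length N.
#' @param feature_names character vector, length p.
#' @param split one of \code{"train"}, \code{"test"}, \code{"unsplit"}.
#' @return an object of class \code{har_dataset} with elements \code{X},
#'   \code{y}, \code{feature_names}, \code{split}, \code{normalized}.
#' @export
har_dataset <- function(X, y, feature_names, split = "unsplit") {
  stopifnot(is.matrix(X), is.numeric(X))
  split <- match.arg(split, c("train", "test", "unsplit"))
  y <- as.integer(y)
  if (length(y) != nrow(X) || length(feature_names) != ncol(X)) {
    stop(sprintf(
      "dimension mismatch: %d feature rows, %d labels, %d columns, %d names",
      nrow(X), length(y), ncol(X), length(feature_names)
    ))
  }
  if (any(y < 1L | y > 6L)) {
    stop("labels must be activity codes in 1..6")
  }
  structure(
    list(
      X = X, y = y, feature_names = as.character(feature_names),
      split = split,
      normalized = all(is.finite(X)) && all(X >= -1 & X <= 1)
    ),
    class = "har_dataset"
  )
}

#' Load a dataset from UCI-HAR dialect files
#'
#' @param features_path whitespace-delimited feature matrix file.
#' @param labels_path one-integer-per-line label file.
#' @param names_path one-name-per-line feature list.
#' @param split split tag for the assembled dataset.
#' @param strict_labels reject labels outside 1..6.
#' @return a \code{har_dataset}.
#' @export
load_dataset <- function(features_path, labels_path, names_path,
                         split = "unsplit", strict_labels = TRUE) {
  X <- read_feature_matrix(features_path)
  y <- read_labels(labels_path, strict = strict_labels)
  nm <- read_feature_names(names_path)
  if (length(y) != nrow(X) || length(nm) != ncol(X)) {
    stop(sprintf(
      "dimension mismatch: features are %dx%d but %d labels and %d names given",
      nrow(X), ncol(X), length(y), length(nm)
    ))
  }
  har_dataset(X, y, nm, split = split)
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf(
    "har_dataset: %d windows x %d features [%s]%s\n",
    nrow(x$X), ncol(x$X), x$split,
    if (x$normalized) ", normalized to [-1,1]" else ""
  ))
  tab <- table(x$y)
  cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Restrict a dataset to a subset of rows
#' @param dataset a \code{har_dataset}.
#' @param rows integer or logical row index.
#' @return a \code{har_dataset} with the selected windows.
#' @export
subset_rows <- function(dataset, rows) {
  stopifnot(inherits(dataset, "har_dataset"))
  har_dataset(dataset$X[rows, , drop = FALSE], dataset$y[rows],
              dataset$feature_names, split = dataset$split)
}
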