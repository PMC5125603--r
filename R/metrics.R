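# Confusion-matrix reporting with the per-class row-rate convention:
# rows are true classes, columns predictions, and each row's rate is
# 100 * diagonal / row total. (Published HAR confusion tables often label
# this column "precision"; arithmetically it is the row-normalized
# per-class recognition rate, so it is called row_rate here.)

round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

new_confusion_report <- function(counts, labels) {
  rtot <- rowSums(counts)
  row_rates <- ifelse(rtot > 0, 100 * diag(counts) / rtot, NA_real_)
  structure(
    list(
      counts = counts, labels = labels, row_rates = row_rates,
      overall_accuracy = 100 * sum(diag(counts)) / sum(counts)
    ),
    class = "confusion_report"
  )
}

#' Confusion matrix with per-class row rates
#'
#' Tallies a K x K count matrix (rows = true class, columns = predicted
#' class) and computes each class's row rate, 100 * diagonal / row total,
#' plus the overall accuracy 100 * trace / total. Rates for classes absent
#' from the truth are reported as \code{NA}, never 0. Full precision is
#' retained internally; rounding (half-up, 2 decimals) happens only in the
#' text rendering.
#'
#' @param y_true true labels. @param y_pred predicted labels, same length.
#' @param labels class codes defining row/column order (default: sorted
#'   union of the observed true labels).
#' @return a \code{confusion_report}.
#' @export
confusion_report <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(y_true), length(y_pred)))
  }
  if (is.null(labels)) labels <- sort(unique(y_true))
  unknown <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(unknown) > 0L) {
    stop("label(s) outside the declared label set: ",
         paste(unknown, collapse = ", "))
  }
  ft <- factor(y_true, levels = labels)
  fp <- factor(y_pred, levels = labels)
  counts <- unclass(table(ft, fp))
  dimnames(counts) <- list(as.character(labels), as.character(labels))
  new_confusion_report(counts, labels)
}

#' Build a confusion report from a precomputed count matrix
#'
#' @param counts K x K nonnegative integer matrix (rows = true class).
#' @param labels K class codes or names.
#' @return a \code{confusion_report}.
#' @export
confusion_report_from_counts <- function(counts, labels) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), length(labels) == nrow(counts),
            all(counts >= 0))
  dimnames(counts) <- list(as.character(labels), as.character(labels))
  new_confusion_report(counts, labels)
}

#' Render a confusion report as a fixed-width text table
#'
#' Class rows, one count column per class and a trailing row-rate column
#' (percent, rounded half-up to 2 decimals; \code{NA} for empty rows).
#'
#' @param report a \code{confusion_report}.
#' @return character vector of table lines.
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "confusion_report"))
  labs <- as.character(report$labels)
  w <- max(nchar(labs), nchar("row_rate"), 8L)
  header <- paste(c(formatC("", width = w),
                    formatC(labs, width = w),
                    formatC("row_rate", width = w)), collapse = " ")
  rows <- vapply(seq_along(labs), function(i) {
    rate <- report$row_rates[i]
    rate_str <- if (is.na(rate)) "NA" else sprintf("%.2f%%", round_half_up(rate))
    paste(c(formatC(labs[i], width = w),
            formatC(report$counts[i, ], width = w),
            formatC(rate_str, width = w)), collapse = " ")
  }, character(1L))
  overall <- sprintf("overall accuracy: %.2f%%",
                     round_half_up(report$overall_accuracy))
  c(header, rows, overall)
}

#' Parse a text table produced by \code{\link{report_text}}
#' @param lines character vector of table lines.
#' @return a \code{confusion_report} rebuilt from the parsed counts.
#' @export
parse_report_text <- function(lines) {
  body <- lines[-1L]
  body <- body[!grepl("^overall", body)]
  toks <- strsplit(trimws(body), "[ \t]+")
  labs <- vapply(toks, `[[`, character(1L), 1L)
  K <- length(labs)
  counts <- t(vapply(toks, function(tk) as.numeric(tk[2:(K + 1L)]), numeric(K)))
  confusion_report_from_counts(counts, labs)
}

#' Write a confusion report as machine-readable TSV
#' @param report a \code{confusion_report}. @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  df <- as.data.frame(report$counts)
  df <- cbind(label = as.character(report$labels), df,
              row_rate = report$row_rates)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.confusion_report <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}
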