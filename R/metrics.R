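#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Any `0/0` is
#' defined as 0 (with a warning), the usual convention for classes never
#' predicted or never present.
#'
#' @param tp,fp,fn Non-negative integer counts (vectorized).
#' @return A data.frame with columns `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(3, 1, 1)  # all 0.75
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
  if (any(tp + fp == 0) || any(tp + fn == 0)) {
    warning("0/0 in precision or recall; defined as 0", call. = FALSE)
  }
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  data.frame(precision = p, recall = r, f1 = f1)
}

#' Recognition accuracy as a percentage
#'
#' The fraction of successful recognition cases over total cases, on the
#' percent scale used by live recognition protocols (e.g. 100 trials per
#' letter).
#'
#' @param n_success,n_total Counts with `0 <= n_success <= n_total`,
#'   `n_total > 0`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' accuracy_percent(30, 100)  # 30
#' @export
accuracy_percent <- function(n_success, n_total) {
  if (n_total <= 0) stop("`n_total` must be positive", call. = FALSE)
  if (n_success < 0 || n_success > n_total) {
    stop("`n_success` must be in [0, n_total]", call. = FALSE)
  }
  100 * n_success / n_total
}

#' Per-class classification report
#'
#' Builds the confusion matrix induced by `truth`/`predicted` over `classes`
#' and reports per-class precision, recall, F1 and support, plus the overall
#' accuracy (confusion-matrix trace over N), the macro average (unweighted
#' class mean) and the weighted average (support-weighted mean). Pure:
#' identical labels give identical reports.
#'
#' @param truth,predicted Equal-length label vectors, values within `classes`.
#' @param classes Class label set; defaults to the sorted union of observed
#'   labels.
#' @return An object of class `eval_report`: list with `per_class`
#'   (data.frame `class`, `precision`, `recall`, `f1`, `support`),
#'   `accuracy`, `macro`, `weighted`, `n`, and the `confusion` matrix
#'   (rows = truth, columns = predicted).
#' @examples
#' rep <- classification_report(c("A", "B", "A"), c("A", "B", "B"))
#' rep$accuracy
#' @export
classification_report <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0) {
    stop(sprintf("labels outside the class set: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  prf <- suppressWarnings(precision_recall_f1(as.numeric(tp), as.numeric(fp),
                                              as.numeric(fn)))
  per_class <- data.frame(class = classes, prf, support = as.integer(support),
                          row.names = NULL)
  n <- length(truth)
  w <- support / n
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / n,
    macro = colMeans(prf),
    weighted = c(precision = sum(w * prf$precision),
                 recall = sum(w * prf$recall),
                 f1 = sum(w * prf$f1)),
    n = n,
    confusion = unclass(cm)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  pc <- x$per_class
  cat(sprintf("%-10s %9s %9s %9s %9s\n", "", "Precision", "Recall", "F1-Score", "Support"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("%-10s %9.*f %9.*f %9.*f %9d\n", pc$class[i],
                digits, pc$precision[i], digits, pc$recall[i],
                digits, pc$f1[i], pc$support[i]))
  }
  cat(sprintf("%-10s %29s %9.*f %9d\n", "Accuracy", "", digits, x$accuracy, x$n))
  cat(sprintf("%-10s %9.*f %9.*f %9.*f %9d\n", "Macro Avg.",
              digits, x$macro[["precision"]], digits, x$macro[["recall"]],
              digits, x$macro[["f1"]], x$n))
  cat(sprintf("%-10s %9.*f %9.*f %9.*f %9d\n", "Wtd. Avg.",
              digits, x$weighted[["precision"]], digits, x$weighted[["recall"]],
              digits, x$weighted[["f1"]], x$n))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' Per-class rows followed by accuracy, macro- and weighted-average rows,
#' mirroring the columns of a standard per-class evaluation table.
#'
#' @param report An `eval_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  pc <- report$per_class
  extra <- data.frame(
    class = c("accuracy", "macro_avg", "weighted_avg"),
    precision = c(NA, report$macro[["precision"]], report$weighted[["precision"]]),
    recall = c(NA, report$macro[["recall"]], report$weighted[["recall"]]),
    f1 = c(report$accuracy, report$macro[["f1"]], report$weighted[["f1"]]),
    support = rep(report$n, 3L))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rbind(pc, extra), path, row.names = FALSE)
  invisible(path)
}
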