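#' Row-normalized confusion matrix
#'
#' Entry `C[i, j] = n_ij / n_i`, where `n_ij` counts samples of true class
#' `i` predicted as class `j` and `n_i` is the support of class `i`. Rows
#' with zero support are all-zero and flagged. Only rows are normalized;
#' column sums need not equal 1.
#'
#' @param true,pred Equal-length label vectors.
#' @param levels Class alphabet (default: the four gait phases).
#' @return List with `C` (row-normalized matrix), `counts` (`n_ij`),
#'   `support` (`n_i`) and `empty_rows`.
#' @export
confusion_matrix <- function(true, pred, levels = gait_phases()) {
  if (length(true) != length(pred)) {
    stop("true and pred differ in length (", length(true), " vs ",
         length(pred), ")")
  }
  tf <- factor(as.character(true), levels = levels)
  pf <- factor(as.character(pred), levels = levels)
  counts <- table(true = tf, pred = pf)
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(true = levels, pred = levels))
  support <- rowSums(counts)
  C <- counts / ifelse(support > 0, support, 1)
  C[support == 0, ] <- 0
  list(C = C, counts = counts, support = support,
       empty_rows = levels[support == 0])
}

per_class_counts <- function(true, pred, levels) {
  tf <- factor(as.character(true), levels = levels)
  pf <- factor(as.character(pred), levels = levels)
  n <- length(tf)
  out <- lapply(levels, function(cl) {
    tp <- sum(tf == cl & pf == cl)
    fp <- sum(tf != cl & pf == cl)
    fn <- sum(tf == cl & pf != cl)
    tn <- n - tp - fp - fn
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  })
  do.call(rbind, stats::setNames(out, levels))
}

safe_div <- function(num, den, what, cl) {
  if (den == 0) {
    warning(what, " undefined for class ", cl,
            " (zero denominator); reporting 0")
    return(0)
  }
  num / den
}

#' Overall and per-class accuracy
#'
#' Overall multi-class accuracy is the fraction of correct predictions.
#' Per-class values use the one-vs-rest form
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param true,pred Equal-length label vectors.
#' @param levels Class alphabet.
#' @return List with `overall` and named per-class `per_class` accuracies.
#' @export
accuracy <- function(true, pred, levels = gait_phases()) {
  if (!length(true)) stop("empty input")
  if (length(true) != length(pred)) stop("true and pred differ in length")
  cc <- per_class_counts(true, pred, levels)
  list(overall = mean(as.character(true) == as.character(pred)),
       per_class = (cc[, "tp"] + cc[, "tn"]) / rowSums(cc))
}

#' Macro-averaged precision, recall and F1
#'
#' Macro-precision and macro-recall are unweighted means of the per-class
#' one-vs-rest precision `TP/(TP+FP)` and recall `TP/(TP+FN)`. Macro-F1 is
#' the harmonic mean of those two macro averages,
#' `2 * P_macro * R_macro / (P_macro + R_macro)` — not the mean of
#' per-class F1 scores, which is also returned (as `mean_class_f1`) for
#' comparison. A class with no predicted (or no true) positives
#' contributes 0 with a warning.
#'
#' @param true,pred Equal-length label vectors.
#' @param levels Class alphabet.
#' @return List with `macro_precision`, `macro_recall`, `macro_f1`,
#'   per-class `precision`, `recall`, `f1`, and `mean_class_f1`.
#' @export
macro_metrics <- function(true, pred, levels = gait_phases()) {
  if (!length(true)) stop("empty input")
  cc <- per_class_counts(true, pred, levels)
  prec <- vapply(levels, function(cl) {
    safe_div(cc[cl, "tp"], cc[cl, "tp"] + cc[cl, "fp"], "precision", cl)
  }, numeric(1))
  rec <- vapply(levels, function(cl) {
    safe_div(cc[cl, "tp"], cc[cl, "tp"] + cc[cl, "fn"], "recall", cl)
  }, numeric(1))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mp <- mean(prec)
  mr <- mean(rec)
  mf1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(macro_precision = mp, macro_recall = mr, macro_f1 = mf1,
       precision = prec, recall = rec, f1 = f1, mean_class_f1 = mean(f1))
}

#' Full evaluation report
#'
#' Bundles overall accuracy, per-class precision/recall/F1, the macro
#' aggregates and the row-normalized confusion matrix.
#'
#' @param true,pred Equal-length label vectors.
#' @param levels Class alphabet.
#' @return A `metrics_report`.
#' @export
metrics_report <- function(true, pred, levels = gait_phases()) {
  acc <- accuracy(true, pred, levels)
  mm <- macro_metrics(true, pred, levels)
  cm <- confusion_matrix(true, pred, levels)
  structure(list(
    n = length(true),
    accuracy = acc$overall,
    class_accuracy = acc$per_class,
    precision = mm$precision, recall = mm$recall, f1 = mm$f1,
    macro_precision = mm$macro_precision, macro_recall = mm$macro_recall,
    macro_f1 = mm$macro_f1, mean_class_f1 = mm$mean_class_f1,
    confusion = cm$C, counts = cm$counts, support = cm$support
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report> n =", x$n, "\n")
  cat(sprintf("  accuracy        %.*f\n", digits, x$accuracy))
  cat(sprintf("  macro-precision %.*f\n", digits, x$macro_precision))
  cat(sprintf("  macro-recall    %.*f\n", digits, x$macro_recall))
  cat(sprintf("  macro-F1        %.*f\n", digits, x$macro_f1))
  per <- round(cbind(precision = x$precision, recall = x$recall, F1 = x$f1),
               digits)
  print(per)
  cat("  row-normalized confusion matrix:\n")
  print(round(x$confusion, digits))
  invisible(x)
}

#' Serialize a metrics report to JSON (and the confusion matrix to CSV)
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path.
#' @param confusion_csv Optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, confusion_csv = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  out <- unclass(report)
  out$confusion <- as.data.frame(out$confusion)
  out$counts <- as.data.frame(out$counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_csv)) {
    utils::write.csv(as.data.frame(report$confusion), confusion_csv)
  }
  invisible(path)
}
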