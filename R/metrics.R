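#' Confusion matrix
#'
#' `counts[i, j]` is the number of records with true class `i` predicted as
#' class `j` (classes coded 0..K-1, displayed with stage labels for K = 4).
#'
#' @param y_true,y_pred integer vectors of class codes in `0..K-1`.
#' @param K number of classes (default 4).
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, K = 4L) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) && (min(y_true, y_pred) < 0L || max(y_true, y_pred) >= K))
    stop("labels out of range 0..", K - 1L, call. = FALSE)
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  if (K == 4L) dimnames(cm) <- list(true = PPG_LABELS, pred = PPG_LABELS)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class and overall classification metrics
#'
#' One-vs-rest marginalization per class `c`: `TP = counts[c, c]`,
#' `FP = colsum - TP`, `FN = rowsum - TP`, `TN = total - TP - FP - FN`; then
#' \itemize{
#'   \item Accuracy  `(TP + TN) / (TP + TN + FP + FN)`
#'   \item Precision `TP / (TP + FP)`
#'   \item Sensitivity (recall) `TP / (TP + FN)`
#'   \item Specificity (true-negative rate) `TN / (TN + FP)`
#'   \item F1 `2 * Pre * Sen / (Pre + Sen)` (harmonic mean)
#' }
#' Overall accuracy is `trace / total`. A 0/0 denominator yields 0 and the
#' affected class is listed in the report's `zero_denominator` flag.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metrics_report`: list with `per_class`
#'   (data.frame with Acc, Pre, Sen, Spe, F1 per class), `overall_accuracy`,
#'   `confusion` and `zero_denominator`.
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  K <- nrow(cm)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  flags <- character(0)
  per <- data.frame(class = if (K == 4L) PPG_LABELS else as.character(seq_len(K) - 1L),
                    Acc = 0, Pre = 0, Sen = 0, Spe = 0, F1 = 0)
  for (c in seq_len(K)) {
    TP <- cm[c, c]
    FP <- sum(cm[, c]) - TP
    FN <- sum(cm[c, ]) - TP
    TN <- total - TP - FP - FN
    pre <- safe_div(TP, TP + FP)
    sen <- safe_div(TP, TP + FN)
    if (TP + FP == 0 || TP + FN == 0 || (pre + sen) == 0)
      flags <- c(flags, per$class[c])
    per$Acc[c] <- (TP + TN) / total
    per$Pre[c] <- pre
    per$Sen[c] <- sen
    per$Spe[c] <- safe_div(TN, TN + FP)
    per$F1[c]  <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
  }
  structure(list(per_class = per,
                 overall_accuracy = sum(diag(cm)) / total,
                 confusion = cm,
                 zero_denominator = unique(flags)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(x))
  invisible(x)
}

#' Format a metrics report as an aligned text table
#'
#' @param report a [metrics_report()].
#' @return a single string with the per-class table and overall accuracy.
#' @export
format_metrics_table <- function(report) {
  per <- report$per_class
  hdr <- sprintf("%-6s %7s %7s %7s %7s %7s\n", "Class", "Acc.", "Pre.", "Sen.", "Spe.", "F1")
  rows <- vapply(seq_len(nrow(per)), function(i)
    sprintf("%-6s %7.4f %7.4f %7.4f %7.4f %7.4f\n",
            per$class[i], per$Acc[i], per$Pre[i], per$Sen[i], per$Spe[i], per$F1[i]), "")
  paste0(hdr, paste(rows, collapse = ""),
         sprintf("Overall accuracy: %.4f\n", report$overall_accuracy),
         if (length(report$zero_denominator))
           sprintf("Zero-denominator convention applied for: %s\n",
                   paste(report$zero_denominator, collapse = ", ")) else "")
}

#' Write / read a metrics report as JSON
#'
#' Schema: `{per_class: {N: {Acc,...}, ...}, overall_accuracy, confusion,
#' zero_denominator}`.
#'
#' @param report a [metrics_report()].
#' @param path JSON path.
#' @return `path` invisibly; `read_metrics_report()` returns the report.
#' @export
write_metrics_report <- function(report, path) {
  per <- report$per_class
  pc <- lapply(seq_len(nrow(per)), function(i)
    as.list(per[i, c("Acc", "Pre", "Sen", "Spe", "F1")]))
  names(pc) <- per$class
  jsonlite::write_json(
    list(per_class = pc,
         overall_accuracy = report$overall_accuracy,
         confusion = unclass(unname(as.matrix(report$confusion))),
         zero_denominator = report$zero_denominator),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  per <- do.call(rbind, lapply(names(x$per_class), function(cl)
    data.frame(class = cl, as.list(x$per_class[[cl]]))))
  cm <- matrix(as.integer(x$confusion), nrow(per), nrow(per), byrow = FALSE)
  if (nrow(per) == 4L) dimnames(cm) <- list(true = PPG_LABELS, pred = PPG_LABELS)
  class(cm) <- c("confusion_matrix", class(cm))
  structure(list(per_class = per, overall_accuracy = x$overall_accuracy,
                 confusion = cm,
                 zero_denominator = as.character(x$zero_denominator)),
            class = "metrics_report")
}
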