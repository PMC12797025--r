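# Binary classification reports: per-class precision/recall/F1/support,
# accuracy, macro and support-weighted aggregates, with zero-division
# flagged and defined as 0.

CLASS_LEVELS <- c("non-binder", "binder")

#' Classification report
#'
#' Computes per-class precision, recall, F1 and support plus accuracy,
#' macro (unweighted mean over classes) and weighted (support-weighted mean)
#' aggregates. A class with zero predicted (or zero true) members gets the
#' affected metric defined as 0 and the report's `zero_division` flag set.
#'
#' @param y_true,y_pred character vectors over `{"binder", "non-binder"}`.
#' @param positive label treated as the positive class in `print` ordering;
#'   metrics are reported for both classes regardless.
#' @return object of class `class_report`: list with `per_class` data.frame,
#'   `accuracy`, `macro`, `weighted`, `support`, `zero_division`.
#' @export
classification_report <- function(y_true, y_pred, positive = "binder") {
  if (length(y_true) == 0) stop("classification_report: empty input")
  if (length(y_true) != length(y_pred))
    stop("classification_report: length mismatch")
  bad <- unique(c(y_true, y_pred))
  bad <- bad[!(bad %in% CLASS_LEVELS)]
  if (length(bad) > 0)
    stop("classification_report: unknown label(s): ", paste(bad, collapse = ", "))

  zero_div <- FALSE
  rows <- lapply(CLASS_LEVELS, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) { zero_div <<- TRUE; 0 } else tp / (tp + fp)
    rec <- if (tp + fn == 0) { zero_div <<- TRUE; 0 } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) { zero_div <<- TRUE; 0 } else
      2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(y_true == cl), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  support <- per_class$support
  w <- support / sum(support)
  structure(list(
    per_class = per_class,
    accuracy = mean(y_true == y_pred),
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              f1 = mean(per_class$f1)),
    weighted = c(precision = sum(w * per_class$precision),
                 recall = sum(w * per_class$recall),
                 f1 = sum(w * per_class$f1)),
    support = sum(support),
    zero_division = zero_div), class = "class_report")
}

#' F1 score from precision and recall
#'
#' Harmonic mean, 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' @noRd
#' @exportS3Method base::print
print.class_report <- function(x, digits = 2, ...) {
  cat(format_class_report(x, digits), sep = "\n")
  invisible(x)
}

#' Format a classification report in the standard table layout
#'
#' Rows Non-binder, Binder, Accuracy, Macro, Weighted; columns Precision,
#' Recall, F1.
#'
#' @param x a `class_report`.
#' @param digits decimal places.
#' @return character vector of report lines.
#' @export
format_class_report <- function(x, digits = 2) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  pc <- x$per_class
  lines <- c(
    sprintf("%-12s%10s%10s%10s", "", "Precision", "Recall", "F1"),
    sprintf("%-12s%10s%10s%10s", "Non-binder",
            fmt(pc$precision[pc$class == "non-binder"]),
            fmt(pc$recall[pc$class == "non-binder"]),
            fmt(pc$f1[pc$class == "non-binder"])),
    sprintf("%-12s%10s%10s%10s", "Binder",
            fmt(pc$precision[pc$class == "binder"]),
            fmt(pc$recall[pc$class == "binder"]),
            fmt(pc$f1[pc$class == "binder"])),
    sprintf("%-12s%10s%10s%10s", "Accuracy", "", "", fmt(x$accuracy)),
    sprintf("%-12s%10s%10s%10s", "Macro", fmt(x$macro[["precision"]]),
            fmt(x$macro[["recall"]]), fmt(x$macro[["f1"]])),
    sprintf("%-12s%10s%10s%10s", "Weighted", fmt(x$weighted[["precision"]]),
            fmt(x$weighted[["recall"]]), fmt(x$weighted[["f1"]])))
  if (x$zero_division)
    lines <- c(lines, "note: zero-division encountered; affected metrics set to 0")
  lines
}

#' Serialize a classification report to a plain list (for JSON output)
#'
#' @param x a `class_report`.
#' @return nested list of numbers.
#' @export
class_report_as_list <- function(x) {
  pc <- split(x$per_class[, c("precision", "recall", "f1", "support")],
              x$per_class$class)
  list(per_class = lapply(pc, as.list),
       accuracy = x$accuracy,
       macro = as.list(x$macro),
       weighted = as.list(x$weighted),
       support = x$support,
       zero_division = x$zero_division)
}
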