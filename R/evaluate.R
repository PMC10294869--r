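#' Construct a 2x2 confusion matrix
#'
#' Counts follow the detection/classification table convention used
#' throughout the package: rows are the output (predicted) class, columns
#' the target (true) class, with the positive class first. `tp` are
#' positives predicted positive, `fp` negatives predicted positive, `fn`
#' positives predicted negative, `tn` negatives predicted negative.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @param positive_name,negative_name Class display names.
#' @return Object of class `confusion_2x2`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn,
                             positive_name = "Damaged",
                             negative_name = "Healthy") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion_matrix: counts must be non-negative integers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 positive_name = positive_name, negative_name = negative_name),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  print(render_matrix_table(x), row.names = FALSE)
  invisible(x)
}

#' Confusion matrix from paired label vectors
#'
#' @param predicted,truth Equal-length vectors of binary labels.
#' @param positive The label treated as the positive class (default: the
#'   first level of `truth`, or `"damaged"` when present).
#' @param positive_name,negative_name Display names (default from labels).
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(predicted, truth, positive = NULL,
                                       positive_name = NULL, negative_name = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("confusion_from_predictions: predicted and truth differ in length")
  labs <- sort(unique(c(predicted, truth)))
  if (length(labs) > 2) stop("confusion_from_predictions: labels must be binary")
  if (is.null(positive)) positive <- if ("damaged" %in% labs) "damaged" else labs[1]
  confusion_matrix(
    tp = sum(predicted == positive & truth == positive),
    fp = sum(predicted == positive & truth != positive),
    fn = sum(predicted != positive & truth == positive),
    tn = sum(predicted != positive & truth != positive),
    positive_name = positive_name %||% positive,
    negative_name = negative_name %||% setdiff(labs, positive)[1] %||% "negative")
}

round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Derived metrics of a 2x2 confusion matrix
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, per-class recalls
#' (`tp/(tp+fn)` for the positive class, `tn/(tn+fp)` for the negative),
#' the two row subtotals (precision and negative predictive value), and the
#' four cell percentages of the grand total. All values are returned raw
#' (percent scale) together with half-up one-decimal roundings under
#' `$rounded`; a metric with a zero denominator is returned as `NA` and
#' listed in `$undefined` rather than raising an error.
#'
#' @param cm A [confusion_matrix()].
#' @return List with elements `accuracy`, `precision`, `recall_positive`,
#'   `recall_negative`, `row_subtotals`, `cell_percentages`, `rounded`,
#'   `undefined`. Percentages throughout (0-100).
#' @export
matrix_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_2x2"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("matrix_metrics: empty matrix")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  m <- list(
    accuracy = ratio(cm$tp + cm$tn, total),
    precision = ratio(cm$tp, cm$tp + cm$fp),
    recall_positive = ratio(cm$tp, cm$tp + cm$fn),
    recall_negative = ratio(cm$tn, cm$tn + cm$fp),
    row_subtotals = c(positive = ratio(cm$tp, cm$tp + cm$fp),
                      negative = ratio(cm$tn, cm$fn + cm$tn)),
    cell_percentages = c(tp = 100 * cm$tp / total, fp = 100 * cm$fp / total,
                         fn = 100 * cm$fn / total, tn = 100 * cm$tn / total))
  m$undefined <- names(Filter(function(v) any(is.na(v)), m[1:4]))
  m$rounded <- lapply(m[c("accuracy", "precision", "recall_positive",
                          "recall_negative", "cell_percentages")],
                      round_half_up)
  m
}

#' Render a confusion matrix in the printed table layout
#'
#' Counts with percent-of-total in parentheses, per-row subtotal column and
#' a subtotal row carrying the two column recalls and overall accuracy.
#'
#' @param cm A [confusion_matrix()].
#' @return A character data frame; parse back with [parse_matrix_table()].
#' @export
render_matrix_table <- function(cm) {
  m <- matrix_metrics(cm)
  cell <- function(count, pct) sprintf("%d (%s%%)", count, fmt_pct(pct))
  pc <- m$cell_percentages
  fmt <- function(x) if (is.na(x)) "-" else paste0(fmt_pct(x), "%")
  data.frame(
    Category = c(cm$positive_name, cm$negative_name, "Subtotal"),
    stats::setNames(data.frame(
      c(cell(cm$tp, pc["tp"]), cell(cm$fn, pc["fn"]), fmt(m$recall_positive)),
      c(cell(cm$fp, pc["fp"]), cell(cm$tn, pc["tn"]), fmt(m$recall_negative)),
      c(fmt(m$row_subtotals["positive"]), fmt(m$row_subtotals["negative"]),
        fmt(m$accuracy)),
      stringsAsFactors = FALSE),
      c(cm$positive_name, cm$negative_name, "Subtotal")),
    check.names = FALSE, stringsAsFactors = FALSE)
}

fmt_pct <- function(x) {
  r <- round_half_up(x, 1)
  ifelse(r == round(r), sprintf("%.0f", r), sprintf("%.1f", r))
}

#' Recover counts from a rendered confusion-matrix table
#'
#' @param tbl A data frame from [render_matrix_table()].
#' @return A [confusion_matrix()].
#' @export
parse_matrix_table <- function(tbl) {
  grab <- function(s) as.integer(sub("^(\\d+) .*$", "\\1", s))
  confusion_matrix(tp = grab(tbl[1, 2]), fp = grab(tbl[1, 3]),
                   fn = grab(tbl[2, 2]), tn = grab(tbl[2, 3]),
                   positive_name = tbl[1, 1], negative_name = tbl[2, 1])
}
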