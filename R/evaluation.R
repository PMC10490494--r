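# Pixel-level confusion counting and the five segmentation metrics:
#   Precision = TP/(TP+FP)         Recall = TP/(TP+FN)
#   F1 = 2*R*P/(R+P)               Accuracy = (TP+TN)/(TP+FP+TN+FN)
#   IoU = TP/(TP+FP+FN)
# Any metric with a zero denominator is reported as NA (undefined),
# never silently as 0 or 1, and excluded from aggregate means.

#' Count pixel-level confusion between a prediction and the ground truth
#'
#' Foreground (1) is the positive class.
#'
#' @param pred,truth binary matrices of identical extent.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes", call. = FALSE)
  pred <- asBinaryMatrix(pred, "pred")
  truth <- asBinaryMatrix(truth, "truth")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  new("ConfusionCounts", tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Compute the five segmentation metrics from confusion counts
#'
#' @param counts a [ConfusionCounts-class] with a positive total.
#' @param imageId id recorded in the report.
#' @return a [MetricReport-class]; metrics with a zero denominator are
#'   `NA`.
#' @examples
#' computeMetrics(new("ConfusionCounts", tp = 50, fp = 10, fn = 10, tn = 30))
#' @export
computeMetrics <- function(counts, imageId = "image") {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  total <- tp + fp + fn + tn
  if (total == 0)
    stop("all confusion counts are zero; nothing to evaluate", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * recall * precision / (recall + precision)
  new("MetricReport",
      accuracy = (tp + tn) / total,
      recall = recall, precision = precision, f1 = f1,
      iou = ratio(tp, tp + fp + fn),
      imageId = as.character(imageId))
}

#' Evaluate predicted masks against ground truth
#'
#' `per_image` mode (the default) scores each pair separately and adds an
#' aggregate report holding the unweighted mean of the defined values of
#' each metric; `pooled` mode sums the confusion counts over all pairs
#' first and reports a single set of metrics.
#'
#' @param preds,truths equal-length aligned lists of binary masks.
#' @param mode `"per_image"` or `"pooled"`.
#' @param ids optional character ids for the reports.
#' @return list with `reports` (per-image [MetricReport-class] objects;
#'   empty in pooled mode) and `aggregate` (one [MetricReport-class]).
#' @export
evaluateDataset <- function(preds, truths, mode = c("per_image", "pooled"),
                            ids = NULL) {
  mode <- match.arg(mode)
  if (length(preds) != length(truths))
    stop(sprintf("got %d predictions but %d truths", length(preds),
                 length(truths)), call. = FALSE)
  if (length(preds) == 0L) stop("nothing to evaluate", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("image%d", seq_along(preds))
  counts <- mapply(confusionCounts, preds, truths, SIMPLIFY = FALSE)
  if (mode == "pooled") {
    pooled <- new("ConfusionCounts",
                  tp = sum(vapply(counts, slot, numeric(1), "tp")),
                  fp = sum(vapply(counts, slot, numeric(1), "fp")),
                  fn = sum(vapply(counts, slot, numeric(1), "fn")),
                  tn = sum(vapply(counts, slot, numeric(1), "tn")))
    return(list(reports = list(),
                aggregate = computeMetrics(pooled, "pooled")))
  }
  reports <- mapply(computeMetrics, counts, ids, SIMPLIFY = FALSE)
  meanOf <- function(nm) {
    v <- vapply(reports, slot, numeric(1), nm)
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  aggregate <- new("MetricReport",
                   accuracy = meanOf("accuracy"), recall = meanOf("recall"),
                   precision = meanOf("precision"), f1 = meanOf("f1"),
                   iou = meanOf("iou"), imageId = "aggregate")
  list(reports = reports, aggregate = aggregate)
}

#' Write an evaluation result as CSV and/or JSON
#'
#' One row per image plus the aggregate row; `NA` marks undefined
#' metrics.
#'
#' @param evalResult the list returned by [evaluateDataset()].
#' @param csvPath,jsonPath destinations; `NULL` skips the format.
#' @return invisibly, the report data frame.
#' @export
writeReport <- function(evalResult, csvPath = NULL, jsonPath = NULL) {
  df <- metricsTable(c(evalResult$reports, list(evalResult$aggregate)))
  if (!is.null(csvPath)) write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(df, jsonPath, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Write a training history as CSV
#'
#' Columns `epoch`, `loss`, `accuracy` — the raw material of
#' loss/accuracy training curves.
#'
#' @param history a [TrainingHistory-class].
#' @param path destination `.csv`.
#' @return invisibly, `path`.
#' @export
writeHistoryCSV <- function(history, path) {
  write.csv(data.frame(epoch = seq_len(history@epochs),
                       loss = history@loss, accuracy = history@accuracy),
            path, row.names = FALSE)
  invisible(path)
}
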