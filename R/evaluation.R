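# Binary-classifier evaluation with the MSI convention: MSI-H tumors are
# the positive class, MSS tumors the negative class.

.align_by_keys <- function(reference, other, what = "predicted") {
  if (is.null(names(reference)) || is.null(names(other))) {
    if (length(reference) != length(other)) {
      stop_key("unnamed label vectors must have equal length")
    }
    names(reference) <- names(other) <- as.character(seq_along(reference))
  }
  only_ref <- setdiff(names(reference), names(other))
  only_oth <- setdiff(names(other), names(reference))
  if (length(only_ref) > 0L || length(only_oth) > 0L) {
    stop_key(sprintf(
      "tumor id sets differ: %d only in reference [%s], %d only in %s [%s]",
      length(only_ref), paste(utils::head(only_ref, 3L), collapse = ", "),
      length(only_oth), what, paste(utils::head(only_oth, 3L), collapse = ", ")))
  }
  list(reference = reference, other = other[names(reference)])
}

#' Confusion counts for MSI predictions
#'
#' Counts TP/FP/TN/FN between reference (e.g. MSI-PCR) and predicted MSI
#' status, with MSI-H as the positive class. Vectors are aligned by tumor
#' id; a mismatch in the id sets is an error listing the difference.
#'
#' @param reference named character vector of reference labels
#'   (`MSS`/`MSI-H`; `MSI-L` is merged into `MSS`).
#' @param predicted named character vector of predicted labels.
#' @return a `confusion_counts` object (list with `TP`, `FP`, `TN`, `FN`).
#' @export
confusion <- function(reference, predicted) {
  al <- .align_by_keys(reference, predicted)
  ref <- normalize_msi_labels(al$reference)
  pred <- normalize_msi_labels(al$other)
  structure(list(
    TP = sum(ref == "MSI-H" & pred == "MSI-H"),
    FP = sum(ref == "MSS" & pred == "MSI-H"),
    TN = sum(ref == "MSS" & pred == "MSS"),
    FN = sum(ref == "MSI-H" & pred == "MSS")
  ), class = "confusion_counts")
}

#' Build confusion counts directly
#' @param TP,FP,TN,FN non-negative integer counts (positive class MSI-H).
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_data("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (positive = MSI-H): TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' The six classification metrics
#'
#' Computes sensitivity (recall) `Se = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)`, precision `Pre = TP/(TP+FP)`, overall accuracy
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, geometric mean `G = sqrt(Se*Sp)` and
#' `F1 = 2*Pre*Se/(Pre+Se)`. A zero denominator is a hard error naming
#' the undefined metric — never a silent NaN.
#'
#' @param counts a `confusion_counts` object.
#' @return a `metric_set`: named list with `Se`, `Sp`, `Pre`, `Acc`,
#'   `GMean`, `F1` (full precision; the print method rounds to 3 d.p.).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (TP + FN == 0) stop_data("sensitivity undefined: no positive (MSI-H) tumors (TP+FN=0)")
  if (TN + FP == 0) stop_data("specificity undefined: no negative (MSS) tumors (TN+FP=0)")
  if (TP + FP == 0) stop_data("precision undefined: no predicted positives (TP+FP=0)")
  se <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  pre <- TP / (TP + FP)
  if (pre + se == 0) stop_data("F1 undefined: precision + sensitivity = 0")
  structure(list(
    Se = se,
    Sp = sp,
    Pre = pre,
    Acc = (TP + TN) / (TP + TN + FP + FN),
    GMean = sqrt(se * sp),
    F1 = 2 * pre * se / (pre + se)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%.3f", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

.check_scores <- function(reference, scores, need_negative = TRUE) {
  al <- .align_by_keys(reference, scores, what = "scores")
  ref <- normalize_msi_labels(al$reference)
  sc <- as.numeric(al$other)
  if (any(!is.finite(sc))) stop_data("scores contain non-finite values")
  if (sum(ref == "MSI-H") == 0L) stop_data("curve undefined: no positive (MSI-H) tumors")
  if (need_negative && sum(ref == "MSS") == 0L) {
    stop_data("curve undefined: no negative (MSS) tumors")
  }
  list(pos = ref == "MSI-H", scores = sc)
}

new_curve <- function(points, area, kind) {
  structure(list(points = points, area = area, kind = kind),
            class = "msi_curve")
}

#' @export
print.msi_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d point(s), area %.4f\n",
              x$kind, nrow(x$points), x$area))
  invisible(x)
}

#' @export
#' @method plot msi_curve
plot.msi_curve <- function(x, ...) {
  lab <- if (x$kind == "ROC") c("False positive rate", "True positive rate")
         else c("Recall", "Precision")
  graphics::plot(x$points$x, x$points$y, type = "l",
                 xlab = lab[1L], ylab = lab[2L],
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("%s curve (area %.3f)", x$kind, x$area), ...)
  if (x$kind == "ROC") graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

#' ROC curve and area from decision scores
#'
#' Sweeps the decision threshold over the distinct score values (ties are
#' grouped into a single threshold), emitting (FPR, TPR) points from
#' (0, 0) to (1, 1); the area is the trapezoidal sum, which equals the
#' probability that a random positive outscores a random negative with
#' ties counted one half.
#'
#' @param reference named `MSS`/`MSI-H` labels.
#' @param scores named numeric decision scores (higher = more MSI-H-like).
#' @return an `msi_curve` with `kind = "ROC"`, `points` (columns `x` =
#'   FPR, `y` = TPR) and `area`.
#' @export
roc_curve <- function(reference, scores) {
  cs <- .check_scores(reference, scores)
  ord <- order(cs$scores, decreasing = TRUE)
  pos <- cs$pos[ord]
  sc <- cs$scores[ord]
  grp_last <- cumsum(rle(sc)$lengths)   # last index of each tied score group
  P <- sum(pos); N <- sum(!pos)
  tpr <- c(0, cumsum(pos)[grp_last] / P)
  fpr <- c(0, cumsum(!pos)[grp_last] / N)
  area <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  new_curve(data.frame(x = fpr, y = tpr), area, "ROC")
}

#' Precision-recall curve and average precision
#'
#' Sweeps thresholds over distinct scores (descending, ties grouped),
#' emitting (recall, precision) points; the area is the average precision
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over the threshold sequence (with
#' \eqn{R_0 = 0}).
#'
#' @inheritParams roc_curve
#' @return an `msi_curve` with `kind = "PR"`, `points` (columns `x` =
#'   recall, `y` = precision) and `area` (average precision).
#' @export
pr_curve <- function(reference, scores) {
  cs <- .check_scores(reference, scores, need_negative = FALSE)
  ord <- order(cs$scores, decreasing = TRUE)
  pos <- cs$pos[ord]
  sc <- cs$scores[ord]
  grp_last <- cumsum(rle(sc)$lengths)
  P <- sum(pos)
  tp <- cumsum(pos)[grp_last]
  n_pred <- grp_last
  recall <- tp / P
  precision <- tp / n_pred
  area <- sum(diff(c(0, recall)) * precision)
  new_curve(data.frame(x = recall, y = precision), area, "PR")
}

#' Per-group evaluation
#'
#' Evaluates predictions (and, when scores are given, ROC/PR curves)
#' separately within each group — typically tumor types. A group where the
#' reference has a single class gets its error message recorded while the
#' other groups are still evaluated.
#'
#' @param reference named `MSS`/`MSI-H` labels.
#' @param predicted optional named predicted labels (for confusion counts
#'   and the six metrics).
#' @param scores optional named decision scores (for ROC/PR curves).
#' @param groups named group label per tumor (e.g. tumor type).
#' @return named list, one element per group, each a list with any of
#'   `confusion`, `metrics`, `roc`, `pr`, `error`.
#' @export
evaluate_by_group <- function(reference, predicted = NULL, scores = NULL,
                              groups) {
  al <- .align_by_keys(reference, groups, what = "groups")
  groups <- al$other
  out <- list()
  for (g in unique(as.character(groups))) {
    ids <- names(groups)[groups == g]
    res <- list()
    err <- tryCatch({
      if (!is.null(predicted)) {
        cm <- confusion(reference[ids], predicted[ids])
        res$confusion <- cm
        res$metrics <- compute_metrics(cm)
      }
      if (!is.null(scores)) {
        res$roc <- roc_curve(reference[ids], scores[ids])
        res$pr <- pr_curve(reference[ids], scores[ids])
      }
      NULL
    }, msiclass_error = function(e) conditionMessage(e))
    if (!is.null(err)) res$error <- err
    out[[g]] <- res
  }
  out
}

#' Write an evaluation report
#'
#' Writes confusion counts, the six metrics, and (when scores are given)
#' ROC/PR areas as a small JSON report, plus the curve point tables as
#' CSVs alongside it.
#'
#' @param reference,predicted,scores as in [evaluate_by_group()].
#' @param path output JSON path; curve CSVs are written next to it with
#'   `_roc.csv` / `_pr.csv` suffixes.
#' @return the report as a list, invisibly.
#' @export
write_evaluation_report <- function(reference, predicted, scores = NULL, path) {
  cm <- confusion(reference, predicted)
  report <- list(confusion = unclass(cm),
                 metrics = lapply(unclass(compute_metrics(cm)), round, 3))
  if (!is.null(scores)) {
    roc <- roc_curve(reference, scores)
    pr <- pr_curve(reference, scores)
    report$roc_auc <- round(roc$area, 3)
    report$average_precision <- round(pr$area, 3)
    base <- sub("\\.json$", "", path)
    utils::write.csv(roc$points, paste0(base, "_roc.csv"), row.names = FALSE)
    utils::write.csv(pr$points, paste0(base, "_pr.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}
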