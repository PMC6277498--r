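# Exploratory cohort statistics: per-feature MSS vs MSI-H comparisons and
# random-forest importance ranking of the feature panel.

.split_classes <- function(x, labels) {
  m <- .as_feature_numeric(x)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  y <- .resolve_labels(labels, ids, x)
  tab <- table(factor(y, levels = c("MSS", "MSI-H")))
  if (any(tab == 0L)) stop_data("both MSS and MSI-H tumors are required")
  list(m = m, y = y, tab = tab)
}

#' Wilcoxon rank-sum comparison of every feature between classes
#'
#' Runs a two-sided Wilcoxon rank-sum (Mann-Whitney) test per feature
#' between MSS and MSI-H tumors via [stats::wilcox.test()] (exact for
#' small untied samples, normal approximation with tie correction
#' otherwise). No multiple-testing correction is applied.
#'
#' @param x feature matrix.
#' @param labels `MSS`/`MSI-H` per row (defaults to labels attached to `x`).
#' @return data frame with one row per feature: `feature`, `statistic`
#'   (the rank-sum W), `p_value`, `median_mss`, `median_msih`.
#' @export
rank_sum_compare <- function(x, labels = NULL) {
  sc <- .split_classes(x, labels)
  if (any(sc$tab < 2L)) stop_data("each class needs at least 2 tumors")
  mss <- sc$m[sc$y == "MSS", , drop = FALSE]
  msih <- sc$m[sc$y == "MSI-H", , drop = FALSE]
  res <- lapply(colnames(sc$m), function(feat) {
    a <- msih[, feat]; b <- mss[, feat]
    if (length(unique(c(a, b))) == 1L) {
      # fully tied: the rank-sum statistic is at its null mean and the
      # tie-corrected variance is 0; the two-sided p-value is 1
      w <- length(a) * length(b) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
      w <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(feature = feat,
               statistic = w,
               p_value = p,
               median_mss = stats::median(mss[, feat]),
               median_msih = stats::median(msih[, feat]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Random-forest importance ranking of the features
#'
#' Fits a seeded random forest (classification, default 500 trees,
#' `sqrt(p)` candidate features per split) and returns mean-decrease-in-
#' impurity (Gini) importance scores, normalized to sum to 1 and sorted
#' descending. The forest is used only to rank features, never as the
#' production classifier.
#'
#' @param x feature matrix.
#' @param labels `MSS`/`MSI-H` per row (defaults to labels attached to `x`).
#' @param trees number of trees (default 500).
#' @param seed integer seed; identical inputs and seed give an identical
#'   ranking.
#' @return data frame with columns `feature` and `importance`
#'   (descending; importances sum to 1).
#' @export
feature_importance <- function(x, labels = NULL, trees = 500, seed = 1) {
  sc <- .split_classes(x, labels)
  y <- factor(sc$y, levels = c("MSS", "MSI-H"))
  fit <- with_seed(seed, {
    randomForest::randomForest(x = sc$m, y = y, ntree = trees)
  })
  imp <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  if (total <= 0) stop_data("random forest produced all-zero importances")
  imp <- imp / total
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord],
             importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
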