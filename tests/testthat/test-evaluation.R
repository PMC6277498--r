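# O(n^2) concordance-probability oracle for the ROC area (ties count 1/2).
concordance_oracle <- function(pos, scores) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

# Exhaustive threshold-enumeration oracle for average precision.
ap_oracle <- function(pos, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (t in th) {
    sel <- scores >= t
    r <- sum(pos & sel) / sum(pos)
    p <- sum(pos & sel) / sum(sel)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

test_that("confusion counting follows the MSI-H-positive convention", {
  fx <- make_confusion_fixture(78, 280, fn = 5, fp = 1)
  cm <- confusion(fx$reference, fx$predicted)
  expect_equal(unclass(cm)[c("TP", "FP", "TN", "FN")],
               list(TP = 73L, FP = 1L, TN = 279L, FN = 5L))

  same <- confusion(fx$reference, fx$reference)
  expect_equal(same$FP + same$FN, 0L)

  other <- setNames(fx$predicted, paste0("X", seq_along(fx$predicted)))
  expect_error(confusion(fx$reference, other), class = "msiclass_key_error")
})

test_that("the six metrics match hand-tallied values and error on empty denominators", {
  m <- compute_metrics(confusion_counts(TP = 73, FP = 1, TN = 279, FN = 5))
  expect_equal(round(unlist(m), 3),
               c(Se = 0.936, Sp = 0.996, Pre = 0.986, Acc = 0.983,
                 GMean = 0.966, F1 = 0.961))

  perfect <- compute_metrics(confusion_counts(10, 0, 10, 0))
  expect_true(all(unlist(perfect) == 1))

  expect_error(compute_metrics(confusion_counts(0, 5, 10, 0)),
               "sensitivity", class = "msiclass_data_error")
  expect_error(compute_metrics(confusion_counts(5, 0, 0, 0)),
               "specificity", class = "msiclass_data_error")
  expect_error(compute_metrics(confusion_counts(0, 0, 10, 5)),
               "precision", class = "msiclass_data_error")
})

test_that("metrics agree with an independent per-sample tally on random labels", {
  for (i in 1:20) {
    n <- 50
    msiclass:::with_seed(400 + i, {
      ref <- sample(c("MSS", "MSI-H"), n, replace = TRUE, prob = c(0.7, 0.3))
      pred <- ifelse(runif(n) < 0.8, ref, sample(c("MSS", "MSI-H"), n, TRUE))
    })
    names(ref) <- names(pred) <- sprintf("T%02d", 1:n)
    if (!all(c("MSS", "MSI-H") %in% ref) || !any(pred == "MSI-H")) next
    cm <- confusion(ref, pred)
    m <- compute_metrics(cm)
    P <- sum(ref == "MSI-H"); N <- n - P
    expect_equal(m$Se, sum(pred == "MSI-H" & ref == "MSI-H") / P)
    expect_equal(m$Sp, sum(pred == "MSS" & ref == "MSS") / N)
    expect_equal(m$Acc, mean(pred == ref))
    # accuracy is the prevalence-weighted average of Se and Sp
    expect_equal(m$Acc, (P * m$Se + N * m$Sp) / (P + N))
    expect_equal(m$GMean, sqrt(m$Se * m$Sp))
  }
})

test_that("ROC handles separation and ties, and equals pairwise concordance", {
  ref <- setNames(rep(c("MSI-H", "MSS"), each = 5), sprintf("T%02d", 1:10))
  sep <- setNames(c(6:10, 1:5), names(ref))
  r <- roc_curve(ref, sep)
  expect_equal(r$area, 1.0)
  expect_equal(unlist(r$points[1, ]), c(x = 0, y = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(x = 1, y = 1))

  flat <- setNames(rep(2, 10), names(ref))
  expect_equal(roc_curve(ref, flat)$area, 0.5)

  expect_error(roc_curve(setNames(rep("MSI-H", 4), sprintf("T%02d", 1:4)),
                         setNames(1:4, sprintf("T%02d", 1:4))),
               class = "msiclass_data_error")

  msiclass:::with_seed(77, {
    labs <- sample(c("MSS", "MSI-H"), 200, replace = TRUE)
    sc <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE)  # plenty of ties
  })
  names(labs) <- names(sc) <- sprintf("T%03d", 1:200)
  expect_equal(roc_curve(labs, sc)$area,
               concordance_oracle(labs == "MSI-H", sc))
  # invariance under a strictly increasing transform
  expect_equal(roc_curve(labs, exp(3 * sc))$area, roc_curve(labs, sc)$area)
})

test_that("ROC area agrees with an established implementation", {
  msiclass:::with_seed(78, {
    labs <- sample(c("MSS", "MSI-H"), 150, replace = TRUE)
    sc <- rnorm(150) + 1.5 * (labs == "MSI-H")
  })
  names(labs) <- names(sc) <- sprintf("T%03d", 1:150)
  ours <- roc_curve(labs, sc)$area
  ref <- suppressMessages(pROC::auc(pROC::roc(labs == "MSI-H", sc)))
  expect_equal(ours, as.numeric(ref))
})

test_that("precision-recall area is the step-summed average precision", {
  ref <- setNames(rep(c("MSI-H", "MSS"), each = 5), sprintf("T%02d", 1:10))
  sep <- setNames(c(6:10, 1:5), names(ref))
  expect_equal(pr_curve(ref, sep)$area, 1.0)

  # constant scores: single threshold, precision = prevalence
  flat <- setNames(rep(1, 10), names(ref))
  expect_equal(pr_curve(ref, flat)$area, 0.5)

  msiclass:::with_seed(79, {
    labs <- sample(c("MSS", "MSI-H"), 120, replace = TRUE, prob = c(0.7, 0.3))
    sc <- sample(seq(0, 1, by = 0.1), 120, replace = TRUE)
  })
  names(labs) <- names(sc) <- sprintf("T%03d", 1:120)
  expect_equal(pr_curve(labs, sc)$area, ap_oracle(labs == "MSI-H", sc))

  all_neg <- setNames(rep("MSS", 5), sprintf("T%02d", 1:5))
  expect_error(pr_curve(all_neg, setNames(1:5, names(all_neg))),
               class = "msiclass_data_error")
})

test_that("per-group evaluation isolates groups and records degenerate ones", {
  fx <- make_confusion_fixture(30, 60, fn = 3, fp = 2)
  groups <- setNames(rep(c("colorectal", "stomach", "endometrial"), 30),
                     names(fx$reference))
  sc <- setNames(ifelse(fx$predicted == "MSI-H", 1, -1) + seq(0, 0.5, length.out = 90),
                 names(fx$reference))
  res <- evaluate_by_group(fx$reference, predicted = fx$predicted,
                           scores = sc, groups = groups)
  expect_named(res, c("colorectal", "stomach", "endometrial"), ignore.order = TRUE)
  expect_s3_class(res$colorectal$roc, "msi_curve")
  expect_s3_class(res$colorectal$pr, "msi_curve")

  # single group equals the ungrouped evaluation
  one <- evaluate_by_group(fx$reference, predicted = fx$predicted,
                           groups = setNames(rep("all", 90), names(fx$reference)))
  expect_equal(unclass(one$all$confusion),
               unclass(confusion(fx$reference, fx$predicted)))

  # a group with a single reference class is reported, others still evaluated
  groups2 <- setNames(rep("mixed", 90), names(fx$reference))
  groups2[which(fx$reference == "MSI-H")[1:5]] <- "pos_only"
  res2 <- evaluate_by_group(fx$reference, predicted = fx$predicted,
                            groups = groups2)
  expect_true(!is.null(res2$pos_only$error))
  expect_s3_class(res2$mixed$metrics, "metric_set")
})
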