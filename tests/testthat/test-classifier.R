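test_that("the stratified splitter rounds half-up per stratum and is reproducible", {
  strata <- rep(c("COAD", "READ", "STAD", "UCEC"), c(377, 131, 437, 487))
  names(strata) <- sprintf("T%04d", seq_along(strata))
  plan <- stratified_split(strata, test_fraction = 0.25, seed = 5)
  expect_length(test_ids(plan), 358L)
  expect_length(intersect(train_ids(plan), test_ids(plan)), 0L)
  # per-stratum counts follow floor(n/4 + 0.5)
  got <- table(plan$assignment$stratum[plan$assignment$set == "test"])
  expect_equal(as.integer(got[c("COAD", "READ", "STAD", "UCEC")]),
               c(94L, 33L, 109L, 122L))

  expect_identical(stratified_split(strata, seed = 5)$assignment,
                   plan$assignment)
  expect_length(test_ids(stratified_split(strata, test_fraction = 0, seed = 1)), 0L)
  expect_error(stratified_split(c(a = "X", b = "Y", c = "Y")),
               "X", class = "msiclass_data_error")
})

test_that("a separable cloud gives perfect CV accuracy and full label recovery", {
  cl <- separable_cloud(n_per_class = 100)
  fit <- msi_fit(cl$x, cl$y, C = c(1, 4, 16), gamma = c(0.01, 0.1),
                 folds = 10, seed = 2)
  expect_true(all(fit$grid$cv_accuracy[fit$grid$C >= 1] == 1))
  expect_equal(unname(predict(fit, cl$x)), cl$y)
  # selected pair attains the grid maximum by construction
  expect_true(all(fit$cv_accuracy >= fit$grid$cv_accuracy))
  # determinism
  fit2 <- msi_fit(cl$x, cl$y, C = c(1, 4, 16), gamma = c(0.01, 0.1),
                  folds = 10, seed = 2)
  expect_identical(c(fit$C, fit$gamma), c(fit2$C, fit2$gamma))
  expect_identical(fit$grid, fit2$grid)
})

test_that("degenerate training inputs are rejected", {
  cl <- separable_cloud(20)
  expect_error(msi_fit(cl$x, rep("MSS", 40), folds = 5),
               class = "msiclass_data_error")
  expect_error(msi_fit(cl$x[1:12, ], cl$y[c(1:10, 21:22)], folds = 10),
               class = "msiclass_data_error")
})

test_that("prediction matches by column name and refuses non-finite input", {
  cl <- separable_cloud(50)
  fit <- msi_fit(cl$x, cl$y, C = 4, gamma = 0.1, folds = 5, seed = 1)
  perm <- cl$x[, c(3, 1, 4, 2)]
  expect_identical(predict(fit, perm), predict(fit, cl$x))
  expect_identical(decision_scores(fit, perm), decision_scores(fit, cl$x))

  bad <- cl$x; bad[1, 2] <- NaN
  expect_error(predict(fit, bad), class = "msiclass_data_error")
  err <- expect_error(predict(fit, cl$x[, 1:3]), class = "msiclass_schema_error")
  expect_match(conditionMessage(err), "f4")
})

test_that("decision scores orient positive toward MSI-H and threshold at zero", {
  cl <- separable_cloud(50)
  fit <- msi_fit(cl$x, cl$y, C = 4, gamma = 0.1, folds = 5, seed = 1)
  sc <- decision_scores(fit, cl$x)
  expect_true(all(is.finite(sc)))
  expect_identical(unname(predict(fit, cl$x) == "MSI-H"), unname(sc > 0))
  # ROC area is invariant under a constant score shift
  a1 <- roc_curve(setNames(cl$y, rownames(cl$x)), sc)$area
  a2 <- roc_curve(setNames(cl$y, rownames(cl$x)), sc + 17)$area
  expect_equal(a1, a2)
})

test_that("scores agree with the SVM library's own decision values", {
  cl <- separable_cloud(60, seed = 9)
  fit <- msi_fit(cl$x, cl$y, C = 4, gamma = 0.05, folds = 5, seed = 1)
  scaled <- scale(cl$x, fit$center, fit$scale)
  ref <- e1071::svm(scaled, factor(cl$y, c("MSS", "MSI-H")), scale = FALSE,
                    kernel = "radial", cost = fit$C, gamma = fit$gamma)
  dv <- drop(attr(predict(ref, scaled, decision.values = TRUE),
                  "decision.values"))
  sc <- decision_scores(fit, cl$x)
  expect_lt(min(max(abs(sc - dv)), max(abs(sc + dv))), 1e-10)
})

test_that("feature scaling is absorbed by standardization", {
  cl <- separable_cloud(50, seed = 21)
  fit1 <- msi_fit(cl$x, cl$y, C = 4, gamma = 0.1, folds = 5, seed = 1)
  x2 <- cl$x; x2[, 1] <- x2[, 1] * 1000
  fit2 <- msi_fit(x2, cl$y, C = 4, gamma = 0.1, folds = 5, seed = 1)
  s1 <- decision_scores(fit1, cl$x)
  s2 <- decision_scores(fit2, x2)
  expect_lt(max(abs(s1 - s2)), 1e-9)
  expect_identical(predict(fit1, cl$x), predict(fit2, x2))
})

test_that("persisted models reload with bit-identical scores", {
  cl <- separable_cloud(50, seed = 13)
  fit <- msi_fit(cl$x, cl$y, C = c(1, 10), gamma = c(0.05, 0.2),
                 folds = 5, seed = 3)
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  fresh <- separable_cloud(25, seed = 14)$x
  expect_identical(decision_scores(fit, fresh), decision_scores(back, fresh))
  expect_identical(back$feature_names, fit$feature_names)

  # truncation is detected
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) %/% 2)], path)
  expect_error(load_model(path), class = "msiclass_data_error")

  # a panel-version mismatch warns and the model's own panel wins
  p2 <- tempfile(fileext = ".json")
  save_model(fit, p2)
  expect_warning(m <- load_model(p2, spec_version = "2"), "panel")
  expect_identical(m$spec_version, fit$spec_version)
})

test_that("held-out accuracy on default synthetic cohorts stays high across seeds", {
  accs <- vapply(1:10, function(s) heldout_accuracy(n_per_class = 40, seed = s),
                 numeric(1))
  expect_true(all(accs >= 0.95))
})
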