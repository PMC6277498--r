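# Two-step MSS / MSI-H classifier: per-feature standardization followed by
# an RBF-kernel support vector machine, with hyperparameters (C, gamma)
# chosen by grid search under stratified 10-fold cross-validation. The
# decision function is evaluated from the model's stored arrays (support
# vectors, dual coefficients, intercept), so a persisted model reproduces
# scores exactly.

.model_format_version <- "msiclass-model-1"

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Stratified 3:1 train/test split
#'
#' Randomly partitions tumors into training and test sets within each
#' stratum (tumor type). The per-stratum test count is
#' `floor(n * test_fraction + 0.5)` (round half up), so strata of sizes
#' 377/131/437/487 at `test_fraction = 0.25` give a 358-tumor test set.
#'
#' @param strata stratum label per tumor: a named character vector or
#'   factor (names are tumor ids; unnamed input is keyed by position).
#' @param test_fraction fraction of each stratum held out (default 0.25).
#' @param seed integer seed; the same seed always yields the same plan.
#' @return a `split_plan`: list with `assignment` (data frame of
#'   `tumor_id`, `stratum`, `set`), `test_fraction`, `seed`.
#' @export
stratified_split <- function(strata, test_fraction = 0.25, seed = 1) {
  strata <- stats::setNames(as.character(strata),
                            if (is.null(names(strata)))
                              as.character(seq_along(strata))
                            else names(strata))
  if (test_fraction < 0 || test_fraction > 1) {
    stop_config("test_fraction must be in [0, 1]")
  }
  sizes <- table(strata)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    stop_data(sprintf("stratum with fewer than 2 tumors: %s",
                      paste(small, collapse = ", ")))
  }
  set_assign <- rep("train", length(strata))
  names(set_assign) <- names(strata)
  with_seed(seed, {
    for (s in names(sizes)) {
      ids <- names(strata)[strata == s]
      n_test <- floor(length(ids) * test_fraction + 0.5)
      if (n_test > 0L) set_assign[sample(ids, n_test)] <- "test"
    }
  })
  structure(list(
    assignment = data.frame(tumor_id = names(strata),
                            stratum = unname(strata),
                            set = unname(set_assign[names(strata)]),
                            stringsAsFactors = FALSE),
    test_fraction = test_fraction,
    seed = seed
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  tab <- table(x$assignment$stratum, x$assignment$set)
  cat(sprintf("Stratified split (test fraction %.3g, seed %d): %d train / %d test\n",
              x$test_fraction, x$seed,
              sum(x$assignment$set == "train"), sum(x$assignment$set == "test")))
  print(tab)
  invisible(x)
}

#' Tumor ids in one side of a split plan
#' @param plan a `split_plan`.
#' @return character vector of tumor ids.
#' @rdname split_ids
#' @export
train_ids <- function(plan) plan$assignment$tumor_id[plan$assignment$set == "train"]

#' @rdname split_ids
#' @export
test_ids <- function(plan) plan$assignment$tumor_id[plan$assignment$set == "test"]

.as_feature_numeric <- function(x, feature_names = NULL) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(m))
    extra <- setdiff(colnames(m), feature_names)
    if (length(missing) > 0L) {
      stop_schema(sprintf(
        "feature columns do not match the model: missing [%s]%s",
        paste(missing, collapse = ", "),
        if (length(extra) > 0L) sprintf(", unexpected [%s]",
                                        paste(extra, collapse = ", "))
        else ""))
    }
    m <- m[, feature_names, drop = FALSE]
  }
  if (any(!is.finite(m))) {
    stop_data("feature matrix contains non-finite values (NA/NaN/Inf)")
  }
  m
}

.resolve_labels <- function(labels, ids, x) {
  if (is.null(labels)) labels <- msi_status(x)
  if (is.null(labels)) stop_data("no MSI status labels supplied or attached")
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0L) {
      stop_key(sprintf("no label for tumor(s): %s",
                       paste(utils::head(missing, 5L), collapse = ", ")))
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop_data("labels length must match number of rows")
  }
  normalize_msi_labels(labels)
}

# Stratified (by class) fold assignment, reproducible for a given seed.
.make_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

.fit_scaler <- function(m) {
  center <- colMeans(m)
  scale_ <- apply(m, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1  # constant column: leave centered only
  list(center = center, scale = scale_)
}

.apply_scaler <- function(m, scaler) {
  scale(m, center = scaler$center, scale = scaler$scale)
}

# RBF cross-kernel between rows of a and rows of b.
.rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

.raw_scores <- function(model, scaled) {
  k <- .rbf_kernel(scaled, model$sv, model$gamma)
  drop(k %*% model$coefs) - model$rho
}

#' Fit the MSS / MSI-H support vector classifier
#'
#' Fits the two-step model: features are standardized (per-feature mean 0,
#' standard deviation 1) and an RBF-kernel SVM is trained on the scaled
#' values. `C` (misclassification cost) and `gamma` (kernel width) are
#' tuned by exhaustive grid search: for every pair, mean accuracy over
#' `folds` class-stratified cross-validation folds is computed (the scaler
#' is refit inside each fold), and the pair with the largest mean CV
#' accuracy wins, ties broken toward the smallest `C` then the smallest
#' `gamma` (the smoother model). The winning pair is then refit on all
#' rows.
#'
#' @param x feature matrix (a `feature_matrix` or any numeric data
#'   frame/matrix with tumor row names and feature column names).
#' @param labels `MSS`/`MSI-H` status per row (character or factor, named
#'   by tumor id or in row order); defaults to the labels attached to `x`.
#'   `MSI-L` is merged into `MSS`.
#' @param C,gamma numeric vectors of grid values. Defaults are the
#'   standard log-2 grids \eqn{C \in 2^{-5}, 2^{-3}, \ldots, 2^{15}} and
#'   \eqn{\gamma \in 2^{-15}, 2^{-13}, \ldots, 2^{3}}.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param spec_version feature-panel version tag stored with the model.
#' @return an `msi_model` with components `feature_names`, `center`,
#'   `scale`, `sv` (support vectors in scaled space), `coefs`, `rho`,
#'   `sign` (orientation so positive scores mean MSI-H), `C`, `gamma`,
#'   `grid` (data frame of all pairs with mean CV accuracy),
#'   `cv_accuracy`, `classes`, `n_class`, `seed`.
#' @seealso [predict.msi_model()], [decision_scores()], [save_model()]
#' @export
msi_fit <- function(x, labels = NULL,
                    C = 2^seq(-5, 15, by = 2),
                    gamma = 2^seq(-15, 3, by = 2),
                    folds = 10, seed = 1,
                    spec_version = attr(x, "spec_version") %||% "1") {
  m <- .as_feature_numeric(x)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  y <- factor(.resolve_labels(labels, ids, x), levels = c("MSS", "MSI-H"))
  tab <- table(y)
  if (any(tab == 0L)) {
    stop_data("training labels must contain both MSS and MSI-H tumors")
  }
  if (any(tab < folds)) {
    stop_data(sprintf("each class needs at least %d (= folds) tumors; have MSS=%d, MSI-H=%d",
                      folds, tab["MSS"], tab["MSI-H"]))
  }

  grid <- expand.grid(C = C, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_

  with_seed(seed, {
    fold <- .make_folds(y, folds)
    for (g in seq_len(nrow(grid))) {
      acc <- numeric(folds)
      for (k in seq_len(folds)) {
        tr <- fold != k
        scaler <- .fit_scaler(m[tr, , drop = FALSE])
        fit <- e1071::svm(.apply_scaler(m[tr, , drop = FALSE], scaler), y[tr],
                          scale = FALSE, kernel = "radial",
                          cost = grid$C[g], gamma = grid$gamma[g])
        pred <- stats::predict(fit, .apply_scaler(m[!tr, , drop = FALSE], scaler))
        acc[k] <- mean(pred == y[!tr])
      }
      grid$cv_accuracy[g] <- mean(acc)
    }
  })

  best_acc <- max(grid$cv_accuracy)
  cand <- grid[grid$cv_accuracy == best_acc, , drop = FALSE]
  cand <- cand[order(cand$C, cand$gamma), , drop = FALSE]
  best <- cand[1L, ]

  scaler <- .fit_scaler(m)
  scaled <- .apply_scaler(m, scaler)
  fit <- e1071::svm(scaled, y, scale = FALSE, kernel = "radial",
                    cost = best$C, gamma = best$gamma)

  model <- structure(list(
    format = .model_format_version,
    feature_names = colnames(m),
    spec_version = as.character(spec_version),
    center = scaler$center,
    scale = scaler$scale,
    gamma = best$gamma,
    C = best$C,
    sv = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    sign = 1,
    classes = c("MSS", "MSI-H"),
    n_class = c(MSS = unname(tab["MSS"]), `MSI-H` = unname(tab["MSI-H"])),
    cv_accuracy = best_acc,
    grid = grid,
    folds = folds,
    seed = seed
  ), class = "msi_model")

  # Orient the decision function so positive scores mean MSI-H. e1071's
  # sign convention follows its internal class ordering; determine it
  # empirically from the fitted model's own training predictions.
  raw <- .raw_scores(model, scaled)
  pred <- stats::predict(fit, scaled)
  agree_pos <- sum((raw > 0) == (pred == "MSI-H"))
  model$sign <- if (agree_pos >= length(raw) - agree_pos) 1 else -1
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msi_model <- function(x, ...) {
  cat("MSS / MSI-H classifier (standardize + RBF-SVM)\n")
  cat(sprintf("  features: %d (panel version %s)\n",
              length(x$feature_names), x$spec_version))
  cat(sprintf("  training: %d MSS, %d MSI-H\n",
              x$n_class[["MSS"]], x$n_class[["MSI-H"]]))
  cat(sprintf("  selected C = %g, gamma = %g (%d-fold CV accuracy %.4f, seed %d)\n",
              x$C, x$gamma, x$folds, x$cv_accuracy, x$seed))
  cat(sprintf("  support vectors: %d\n", nrow(x$sv)))
  invisible(x)
}

#' @export
#' @method summary msi_model
summary.msi_model <- function(object, ...) {
  print(object)
  g <- object$grid[order(-object$grid$cv_accuracy,
                         object$grid$C, object$grid$gamma), ]
  cat("\nTop grid points by mean CV accuracy:\n")
  print(utils::head(g, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
#' @method plot msi_model
plot.msi_model <- function(x, ...) {
  Cs <- sort(unique(x$grid$C))
  gs <- sort(unique(x$grid$gamma))
  z <- matrix(NA_real_, length(Cs), length(gs))
  for (i in seq_len(nrow(x$grid))) {
    z[match(x$grid$C[i], Cs), match(x$grid$gamma[i], gs)] <- x$grid$cv_accuracy[i]
  }
  graphics::image(log2(Cs), log2(gs), z,
                  xlab = "log2 C", ylab = "log2 gamma",
                  main = "Grid-search mean CV accuracy", ...)
  graphics::points(log2(x$C), log2(x$gamma), pch = 4, cex = 2)
  invisible(x)
}

#' Predict MSI status or decision scores
#'
#' Applies the stored scaler and the RBF decision function
#' \eqn{f(x) = \sum_i \alpha_i K(s_i, x) - \rho} (evaluated from the
#' model's stored support vectors and coefficients). A tumor is called
#' MSI-H iff its score is strictly positive. Feature columns are matched
#' by name and reordered as needed; missing or non-finite features are an
#' error, never a silent prediction.
#'
#' @param object an `msi_model`.
#' @param newdata feature matrix with the model's feature columns.
#' @param type `"class"` for MSS/MSI-H labels, `"score"` for the signed
#'   decision value (positive = MSI-H side).
#' @param ... unused.
#' @return named vector keyed by tumor id.
#' @export
predict.msi_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  m <- .as_feature_numeric(newdata, feature_names = object$feature_names)
  scaled <- .apply_scaler(m, list(center = object$center, scale = object$scale))
  score <- object$sign * .raw_scores(object, scaled)
  names(score) <- rownames(m)
  if (type == "score") return(score)
  stats::setNames(ifelse(score > 0, "MSI-H", "MSS"), names(score))
}

#' Decision scores of the classifier
#'
#' Convenience wrapper for `predict(model, x, type = "score")`: the signed
#' distance-like SVM decision value per tumor, positive on the MSI-H side.
#' Thresholding at 0 reproduces the class predictions exactly; the scores
#' are the inputs for ROC and precision-recall curves.
#'
#' @param model an `msi_model`.
#' @param x feature matrix.
#' @return named numeric vector keyed by tumor id.
#' @export
decision_scores <- function(model, x) predict(model, x, type = "score")

.num_out <- function(x) sprintf("%.17g", as.numeric(x))
.num_in <- function(x) as.numeric(x)

#' Persist a trained classifier
#'
#' Writes the model as a versioned JSON container holding explicit arrays
#' (feature names, scaler mean/sd, support vectors, dual coefficients,
#' intercept, C, gamma, classes, seed) rather than opaque serialization.
#' Numeric arrays are stored as full-precision decimal strings, so a
#' loaded model reproduces decision scores bit-identically.
#'
#' @param model an `msi_model`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @rdname model_io
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "msi_model"))
  payload <- list(
    format = model$format,
    feature_names = model$feature_names,
    spec_version = model$spec_version,
    classes = model$classes,
    C = .num_out(model$C),
    gamma = .num_out(model$gamma),
    sign = model$sign,
    rho = .num_out(model$rho),
    center = .num_out(model$center),
    scale = .num_out(model$scale),
    coefs = .num_out(model$coefs),
    sv = .num_out(as.numeric(model$sv)),
    sv_dim = dim(model$sv),
    n_class = as.list(model$n_class),
    cv_accuracy = model$cv_accuracy,
    folds = model$folds,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @param path model file written by [save_model()].
#' @param spec_version optional feature-panel version the caller expects;
#'   on mismatch a warning is issued and the model's own version wins.
#' @return for `load_model()`: the restored `msi_model`.
#' @rdname model_io
#' @export
load_model <- function(path, spec_version = NULL) {
  if (!file.exists(path)) stop_data(sprintf("model file not found: %s", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop_data(sprintf("corrupt or unreadable model file %s: %s",
                                          path, conditionMessage(e)))
                      })
  if (!identical(payload$format, .model_format_version)) {
    stop_data(sprintf("unsupported model file format '%s' (expected '%s')",
                      payload$format %||% "<missing>", .model_format_version))
  }
  needed <- c("feature_names", "center", "scale", "coefs", "sv", "sv_dim",
              "rho", "C", "gamma", "sign", "classes")
  missing <- setdiff(needed, names(payload))
  if (length(missing) > 0L) {
    stop_data(sprintf("model file %s is missing field(s): %s",
                      path, paste(missing, collapse = ", ")))
  }
  if (!is.null(spec_version) &&
      !identical(as.character(spec_version), payload$spec_version)) {
    warning(sprintf(
      "model was trained under feature panel version '%s' (caller configured '%s'); using the model's own panel",
      payload$spec_version, spec_version), call. = FALSE)
  }
  sv <- matrix(.num_in(payload$sv), nrow = payload$sv_dim[1L],
               ncol = payload$sv_dim[2L])
  structure(list(
    format = payload$format,
    feature_names = payload$feature_names,
    spec_version = payload$spec_version,
    center = stats::setNames(.num_in(payload$center), payload$feature_names),
    scale = stats::setNames(.num_in(payload$scale), payload$feature_names),
    gamma = .num_in(payload$gamma),
    C = .num_in(payload$C),
    sv = sv,
    coefs = .num_in(payload$coefs),
    rho = .num_in(payload$rho),
    sign = payload$sign,
    classes = payload$classes,
    n_class = unlist(payload$n_class),
    cv_accuracy = payload$cv_accuracy,
    grid = NULL,
    folds = payload$folds,
    seed = payload$seed
  ), class = "msi_model")
}
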