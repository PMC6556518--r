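# Stacked generalization: out-of-fold prediction matrix over inner folds,
# level-2 LASSO meta-model on the raw (unstandardized) predictions, and
# deployment via level-1 learners refit on the full training set.

#' Repeated random train/test splits
#'
#' @param sample_ids Character vector of sample ids.
#' @param repeats Number of independent splits.
#' @param test_fraction Held-out fraction (default 1/10, the 9:1 ratio).
#' @param seed Integer seed.
#' @return List of split plans, each with `repeat_index`, `train_ids`,
#'   `test_ids`.
#' @export
make_splits <- function(sample_ids, repeats = 10L, test_fraction = 0.1,
                        seed = 1L) {
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (n < 20L) stop("need at least 20 samples for a 9:1 split protocol")
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n) {
    stop("test fraction ", test_fraction, " is infeasible for n = ", n)
  }
  with_seed(substream_seed(seed, "splits"), {
    lapply(seq_len(repeats), function(r) {
      test <- sort(sample(sample_ids, n_test))
      list(repeat_index = r,
           train_ids = setdiff(sample_ids, test),
           test_ids = test)
    })
  })
}

#' Export split plans to a tidy table
#'
#' @param splits Result of [make_splits()].
#' @return Tibble with columns `repeat_index`, `sample_id`, `role`.
#' @export
splits_to_table <- function(splits) {
  do.call(rbind, lapply(splits, function(s) {
    tibble::tibble(
      repeat_index = s$repeat_index,
      sample_id = c(s$train_ids, s$test_ids),
      role = rep(c("train", "test"),
                 c(length(s$train_ids), length(s$test_ids))))
  }))
}

#' Out-of-fold prediction matrix for the level-2 model
#'
#' Training samples are partitioned into `folds` inner folds; for each
#' fold and each learner, the standardizer and the learner are fit on the
#' remaining folds only and predictions are made for the held fold, so
#' every entry comes from a model that never saw that sample.
#'
#' @param X Raw training spectra matrix (samples x bands).
#' @param y Training trait vector.
#' @param specs Named list of [learner_spec()] objects.
#' @param folds Number of inner folds (default 10).
#' @param seed Integer seed (fold assignment and learner substreams).
#' @return Numeric matrix (n x length(specs)) of out-of-fold predictions
#'   with learner names as columns and sample ids as rownames; the fold
#'   assignment is attached as attribute `"folds"`.
#' @export
build_oos_matrix <- function(X, y, specs, folds = 10L, seed = 1L) {
  check_spectra_matrix(X, "X")
  n <- nrow(X)
  if (n != length(y)) stop("rows of X must match length of y")
  if (n < 2L * folds) stop("need at least 2 x folds training samples")
  fold_id <- make_cv_folds(n, folds, substream_seed(seed, "folds"))
  if (min(table(fold_id)) < 2L) stop("a fold has fewer than 2 samples")
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$kind, character(1))
  }
  oos <- matrix(NA_real_, n, length(specs),
                dimnames = list(rownames(X), names(specs)))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    std <- fit_standardizer(X[tr, , drop = FALSE])
    Ztr <- apply_standardizer(std, X[tr, , drop = FALSE])
    Zte <- apply_standardizer(std, X[!tr, , drop = FALSE])
    for (k in seq_along(specs)) {
      model <- fit_learner(specs[[k]], Ztr, y[tr])
      oos[!tr, k] <- predict_learner(model, Zte)
    }
  }
  attr(oos, "folds") <- fold_id
  oos
}

#' Fit a stacked regression model
#'
#' Builds the out-of-fold prediction matrix, fits the level-2 LASSO on it
#' (intercept included, predictions deliberately *not* standardized, with
#' the penalty chosen by 10-fold CV minimizing RMSE and ties resolved
#' toward the larger penalty), then refits the level-1 learners and the
#' standardizer on the full training set for deployment.
#'
#' @inheritParams build_oos_matrix
#' @return An object of class `stack_model` with the refit level-1
#'   learners, level-2 intercept/weights/penalty, the training
#'   standardizer, the OOS matrix and the level-2 in-sample fitted values.
#' @export
fit_stack <- function(X, y, specs, folds = 10L, seed = 1L) {
  oos <- build_oos_matrix(X, y, specs, folds, seed)
  l2 <- fit_level2_lasso(oos, y, seed)
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  level1 <- lapply(specs, function(s) fit_learner(s, Z, y))
  names(level1) <- colnames(oos)
  structure(list(
    level1 = level1,
    standardizer = std,
    level2_intercept = l2$intercept,
    level2_coefficients = l2$weights,
    level2_penalty = l2$lambda,
    oos_matrix = oos,
    oos_fitted = l2$fitted,
    specs = specs,
    seed = seed
  ), class = "stack_model")
}

# level-2 LASSO on the OOS matrix; no standardization by design
fit_level2_lasso <- function(oos, y, seed) {
  foldid <- make_cv_folds(nrow(oos), 10L, substream_seed(seed, "level2"))
  cvfit <- glmnet::cv.glmnet(oos, y, alpha = 1, foldid = foldid,
                             nlambda = 100L, standardize = FALSE,
                             thresh = 1e-12)
  lam <- max(cvfit$lambda[cvfit$cvm <= min(cvfit$cvm) + 1e-12])
  co <- as.numeric(stats::coef(cvfit$glmnet.fit, s = lam))
  weights <- co[-1L]
  names(weights) <- colnames(oos)
  list(intercept = co[1L], weights = weights, lambda = lam,
       fitted = as.numeric(co[1L] + oos %*% weights))
}

#' Predict from a stacked model
#'
#' Applies the model's training standardizer to the raw spectra, gets each
#' refit level-1 learner's prediction, and combines them with the level-2
#' affine rule `intercept + sum_k w_k * pred_k`.
#'
#' @param model A [fit_stack()] result.
#' @param X Raw spectra matrix containing the training bands.
#' @param level1 If `TRUE`, also return the per-learner predictions.
#' @return Numeric predictions, or a list with `stack` and `level1` when
#'   `level1 = TRUE`.
#' @export
predict_stack <- function(model, X, level1 = FALSE) {
  stopifnot(inherits(model, "stack_model"))
  Z <- apply_standardizer(model$standardizer, X)
  preds <- vapply(model$level1, function(m) predict_learner(m, Z),
                  numeric(nrow(Z)))
  if (nrow(Z) == 1L) preds <- matrix(preds, nrow = 1L,
                                     dimnames = list(rownames(Z),
                                                     names(model$level1)))
  stacked <- as.numeric(model$level2_intercept +
                          preds %*% model$level2_coefficients)
  names(stacked) <- rownames(Z)
  if (level1) list(stack = stacked, level1 = preds) else stacked
}

#' Level-2 coefficient table
#'
#' @param model A [fit_stack()] result.
#' @return Tibble with one row per learner (`learner`, `weight`); the
#'   intercept is attached as attribute `"intercept"`.
#' @export
level2_coefficients <- function(model) {
  stopifnot(inherits(model, "stack_model"))
  out <- tibble::tibble(learner = names(model$level2_coefficients),
                        weight = as.numeric(model$level2_coefficients))
  attr(out, "intercept") <- model$level2_intercept
  out
}

#' @export
print.stack_model <- function(x, ...) {
  cat("stacked regression model:", length(x$level1), "level-1 learners\n")
  cat(sprintf("  level-2 lambda = %.4g, intercept = %.3f\n",
              x$level2_penalty, x$level2_intercept))
  w <- x$level2_coefficients
  cat("  weights:", paste(sprintf("%s=%.3f", names(w), w),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a stacked model to a JSON envelope
#'
#' The envelope stores the level-2 parameters in clear JSON and each
#' level-1 learner (plus the standardizer) as a base64 blob of serialized
#' R state, so a reloaded model reproduces predictions bit-identically.
#'
#' @param model A `stack_model`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
save_stack_model <- function(model, path) {
  stopifnot(inherits(model, "stack_model"))
  payload <- list(level1 = model$level1,
                  standardizer = model$standardizer,
                  level2_intercept = model$level2_intercept,
                  level2_coefficients = model$level2_coefficients,
                  level2_penalty = model$level2_penalty,
                  specs = model$specs, seed = model$seed)
  envelope <- list(
    class = "stack_model",
    # clear-text metadata for inspection; the blob is authoritative and
    # restores the exact doubles
    level2 = list(intercept = model$level2_intercept,
                  weights = as.list(model$level2_coefficients),
                  penalty = model$level2_penalty),
    learners = lapply(model$level1, function(m) {
      list(kind = m$kind, chosen = m$chosen)
    }),
    model_blob = jsonlite::base64_enc(serialize(payload, NULL)),
    seed = model$seed
  )
  writeLines(jsonlite::toJSON(envelope, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Restore a stacked model from its JSON envelope
#'
#' @param path File written by [save_stack_model()].
#' @return A `stack_model` (without the training OOS matrix).
#' @export
load_stack_model <- function(path) {
  env <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(env$class, "stack_model")) {
    stop("not a stack_model envelope: ", path)
  }
  payload <- unserialize(jsonlite::base64_dec(env$model_blob))
  structure(list(
    level1 = payload$level1,
    standardizer = payload$standardizer,
    level2_intercept = payload$level2_intercept,
    level2_coefficients = payload$level2_coefficients,
    level2_penalty = payload$level2_penalty,
    oos_matrix = NULL,
    oos_fitted = NULL,
    specs = payload$specs,
    seed = payload$seed
  ), class = "stack_model")
}
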