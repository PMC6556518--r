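# Metrics, the repeated train/test benchmark protocol (train-with-CV /
# train-without-CV / test phases), band-block ablation importance, and
# trait summary tables.

#' Coefficient of determination
#'
#' `R2 = 1 - SSE/SST` (not a squared correlation); may be negative when
#' the predictions do worse than the mean.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param yhat Predictions.
#' @return Dimensionless R2.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant y: R2 undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean squared error
#'
#' @param y Observed values.
#' @param yhat Predictions.
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) == 0L) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Repeated 9:1 benchmark of the six learners and the stack
#'
#' For each repeat: split the samples 9:1; on the training part build the
#' stack (which yields out-of-fold predictions for the train-with-CV
#' phase and full-training refits); score three phases per model:
#' `train_cv` (out-of-fold predictions vs training truth; the stack's are
#' its level-2 fitted values on the OOS matrix), `train_full`
#' (full-training refits applied back to the training data) and `test`
#' (deployed models on the held-out tenth).
#'
#' @param X Raw spectra matrix.
#' @param y Named trait vector aligned with `rownames(X)`.
#' @param specs Named list of [learner_spec()] objects.
#' @param repeats Number of independent 9:1 splits.
#' @param folds Inner folds for the OOS matrix.
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed.
#' @param trait Label recorded in the output (e.g. `"vcmax"`).
#' @return List of class `eval_summary` with `results` (tidy tibble:
#'   `trait`, `repeat_index`, `model`, `phase`, `metric`, `value`) and
#'   `summary` (mean and sd per model/phase/metric).
#' @export
run_benchmark <- function(X, y, specs, repeats = 10L, folds = 10L,
                          test_fraction = 0.1, seed = 1L,
                          trait = "trait") {
  check_spectra_matrix(X, "X")
  if (is.null(names(y))) names(y) <- rownames(X)
  ids <- rownames(X)
  stopifnot(all(ids %in% names(y)))
  y <- y[ids]
  splits <- make_splits(ids, repeats = repeats,
                        test_fraction = test_fraction, seed = seed)
  rows <- list()
  add <- function(rep_i, model, phase, yy, pp) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      trait = trait, repeat_index = rep_i, model = model, phase = phase,
      metric = c("r_squared", "rmse"),
      value = c(r_squared(yy, pp), rmse(yy, pp)))
  }
  for (s in splits) {
    Xtr <- X[s$train_ids, , drop = FALSE]
    Xte <- X[s$test_ids, , drop = FALSE]
    ytr <- y[s$train_ids]; yte <- y[s$test_ids]
    stack <- fit_stack(Xtr, ytr, specs, folds = folds,
                       seed = seed + 131L * s$repeat_index)
    # train-with-CV: out-of-fold provenance
    for (k in colnames(stack$oos_matrix)) {
      add(s$repeat_index, k, "train_cv", ytr, stack$oos_matrix[, k])
    }
    add(s$repeat_index, "stack", "train_cv", ytr, stack$oos_fitted)
    # train-without-CV and test: full-training refits
    pr_tr <- predict_stack(stack, Xtr, level1 = TRUE)
    pr_te <- predict_stack(stack, Xte, level1 = TRUE)
    for (k in colnames(pr_tr$level1)) {
      add(s$repeat_index, k, "train_full", ytr, pr_tr$level1[, k])
      add(s$repeat_index, k, "test", yte, pr_te$level1[, k])
    }
    add(s$repeat_index, "stack", "train_full", ytr, pr_tr$stack)
    add(s$repeat_index, "stack", "test", yte, pr_te$stack)
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ trait + model + phase + metric,
                          data = results,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- tibble::tibble(
    trait = agg$trait, model = agg$model, phase = agg$phase,
    metric = agg$metric, mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  structure(list(results = results, summary = summary,
                 repeats = repeats, trait = trait),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("benchmark of", length(unique(x$summary$model)), "models over",
      x$repeats, "repeats (trait:", x$trait, ")\n")
  tst <- x$summary[x$summary$phase == "test", ]
  for (m in unique(tst$model)) {
    r2 <- tst$mean[tst$model == m & tst$metric == "r_squared"]
    rm <- tst$mean[tst$model == m & tst$metric == "rmse"]
    cat(sprintf("  %-6s test R2 = %.3f, RMSE = %.2f\n", m, r2, rm))
  }
  invisible(x)
}

#' Band-block ablation importance
#'
#' For each repetition: draw a fresh 9:1 split; for each learner, fit on
#' the full spectrum (the per-repetition baseline) and record the test
#' R2; then for each band block, refit on the spectrum with that block
#' excluded and record the percent change
#' `100 * (R2_excluded - R2_baseline) / R2_baseline`. The table averages
#' these over repetitions.
#'
#' @param X Raw spectra matrix.
#' @param y Named trait vector.
#' @param specs Named list of [learner_spec()] objects.
#' @param blocks Block table from [make_band_blocks()].
#' @param repetitions Number of independent resplits.
#' @param test_fraction Held-out fraction per repetition.
#' @param seed Integer seed.
#' @return List of class `importance_table` with `table` (tibble:
#'   `learner`, `block`, `mean_pct_change`), the per-repetition `raw`
#'   values, and `repetitions`.
#' @export
block_importance <- function(X, y, specs, blocks = make_band_blocks(),
                             repetitions = 100L, test_fraction = 0.1,
                             seed = 1L) {
  check_spectra_matrix(X, "X")
  if (is.null(names(y))) names(y) <- rownames(X)
  y <- y[rownames(X)]
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$kind, character(1))
  }
  splits <- make_splits(rownames(X), repeats = repetitions,
                        test_fraction = test_fraction,
                        seed = substream_seed(seed, "importance"))
  raw <- array(NA_real_,
               dim = c(repetitions, nrow(blocks), length(specs)),
               dimnames = list(NULL, blocks$label, names(specs)))
  for (s in splits) {
    Xtr <- X[s$train_ids, , drop = FALSE]
    Xte <- X[s$test_ids, , drop = FALSE]
    ytr <- y[s$train_ids]; yte <- y[s$test_ids]
    std <- fit_standardizer(Xtr)
    Ztr <- apply_standardizer(std, Xtr)
    Zte <- apply_standardizer(std, Xte)
    for (k in names(specs)) {
      base_fit <- fit_learner(specs[[k]], Ztr, ytr)
      base_r2 <- r_squared(yte, predict_learner(base_fit, Zte))
      for (b in seq_len(nrow(blocks))) {
        Ztr_b <- exclude_blocks(Ztr, blocks[b, ])
        Zte_b <- exclude_blocks(Zte, blocks[b, ])
        fit_b <- fit_learner(specs[[k]], Ztr_b, ytr)
        r2_b <- r_squared(yte, predict_learner(fit_b, Zte_b))
        raw[s$repeat_index, b, k] <- 100 * (r2_b - base_r2) / base_r2
      }
    }
  }
  tab <- expand.grid(block = blocks$label, learner = names(specs),
                     stringsAsFactors = FALSE)
  tab$mean_pct_change <- mapply(function(b, k) mean(raw[, b, k]),
                                tab$block, tab$learner)
  structure(list(table = tibble::as_tibble(tab[, c("learner", "block",
                                                   "mean_pct_change")]),
                 raw = raw, repetitions = repetitions),
            class = "importance_table")
}

#' Trait summary table
#'
#' Per genotype and overall: sample counts, min-max range, mean, SD and
#' fold change (max/min) for Vc,max and J1800. The overall mean equals
#' the sample-size-weighted mean of the genotype means by construction.
#'
#' @param records Tibble with columns `genotype`, `vcmax` and optionally
#'   `j1800` (NA allowed).
#' @return Tibble with one row per genotype plus an `Overall` row.
#' @export
summarize_traits <- function(records) {
  if (nrow(records) < 1L) stop("need at least one trait record")
  if (any(records$vcmax <= 0, na.rm = TRUE)) {
    stop("non-positive vcmax values")
  }
  has_j <- "j1800" %in% names(records)
  if (has_j && any(records$j1800 <= 0, na.rm = TRUE)) {
    stop("non-positive j1800 values")
  }
  one <- function(df, label) {
    j <- if (has_j) df$j1800[!is.na(df$j1800)] else numeric(0)
    tibble::tibble(
      genotype = label,
      n = nrow(df),
      n_j = length(j),
      vcmax_min = min(df$vcmax), vcmax_max = max(df$vcmax),
      vcmax_mean = mean(df$vcmax), vcmax_sd = stats::sd(df$vcmax),
      vcmax_fold = max(df$vcmax) / min(df$vcmax),
      j_min = if (length(j)) min(j) else NA_real_,
      j_max = if (length(j)) max(j) else NA_real_,
      j_mean = if (length(j)) mean(j) else NA_real_,
      j_sd = if (length(j) > 1L) stats::sd(j) else NA_real_,
      j_fold = if (length(j)) max(j) / min(j) else NA_real_)
  }
  per <- lapply(split(records, records$genotype), function(df) {
    one(df, df$genotype[1L])
  })
  rbind(do.call(rbind, per[unique(records$genotype)]),
        one(records, "Overall"))
}

#' Summary arithmetic on a genotype roster
#'
#' Computes the overall trait statistics implied by a roster of
#' [genotype_spec()] objects: the overall Vc,max range (union of genotype
#' ranges), its fold change, and the sample-size-weighted mean of the
#' genotype means.
#'
#' @param genotypes List of [genotype_spec()] objects.
#' @return Tibble with `n`, `n_j`, `vcmax_min`, `vcmax_max`,
#'   `vcmax_fold`, `vcmax_weighted_mean`.
#' @export
roster_summary <- function(genotypes = tobacco_genotypes()) {
  n <- vapply(genotypes, function(g) g$n_samples, integer(1))
  lo <- vapply(genotypes, function(g) g$vcmax_range[1], numeric(1))
  hi <- vapply(genotypes, function(g) g$vcmax_range[2], numeric(1))
  mu <- vapply(genotypes, function(g) g$vcmax_mean, numeric(1))
  jobs <- vapply(genotypes, function(g) g$j_observed, logical(1))
  n_total <- sum(n)
  n_j <- sum(n[jobs])
  wmean <- sum(n * mu) / n_total
  tibble::tibble(
    n = n_total, n_j = n_j,
    vcmax_min = min(lo), vcmax_max = max(hi),
    vcmax_fold = max(hi) / min(lo),
    vcmax_weighted_mean = wmean)
}
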