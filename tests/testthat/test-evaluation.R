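test_that("R2 is the coefficient of determination, not a correlation", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1.1, 1.9, 3.2)), 0.97)
  # worse than the mean goes negative
  expect_lt(r_squared(y, c(3, 1, 2)), 0)
  expect_error(r_squared(rep(1, 3), y), "constant")
  # shift applied to both y and yhat leaves R2 unchanged
  yh <- c(1.2, 2.1, 2.7)
  expect_equal(r_squared(y + 5, yh + 5), r_squared(y, yh))
})

test_that("RMSE behaves as the root mean squared residual", {
  y <- c(2, 4, 6, 8)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 3), 3)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("the benchmark reports every model, phase and repeat", {
  d <- coarse_dataset(seed = 9, step = 25)
  idx <- 1:80
  bench <- run_benchmark(d$X[idx, ], d$y[idx], fast_specs(), repeats = 3,
                         folds = 5, seed = 5, trait = "vcmax")
  res <- bench$results
  # (2 learners + stack) x 3 phases x 3 repeats x 2 metrics
  expect_equal(nrow(res), 3L * 3L * 3L * 2L)
  expect_setequal(unique(res$model), c("LASSO", "PLS", "stack"))
  expect_setequal(unique(res$phase), c("train_cv", "train_full", "test"))
  expect_true(all(res$value[res$metric == "rmse"] >= 0))
  expect_equal(nrow(bench$summary), 3L * 3L * 2L)
  # deterministic under the same seed
  bench2 <- run_benchmark(d$X[idx, ], d$y[idx], fast_specs(), repeats = 3,
                          folds = 5, seed = 5, trait = "vcmax")
  expect_identical(bench$results, bench2$results)
})

test_that("vacuous block exclusion changes nothing", {
  d <- coarse_dataset(seed = 10, step = 25)
  blocks <- make_band_blocks()
  f_block <- blocks[blocks$label == "F", ]
  X_pre <- exclude_blocks(d$X[1:60, ], f_block)  # F already removed
  imp <- block_importance(X_pre, d$y[1:60],
                          list(PLS = learner_spec("PLS",
                                                  grid = list(ncomp = 3L),
                                                  seed = 1)),
                          blocks = f_block, repetitions = 2, seed = 3)
  expect_true(all(imp$table$mean_pct_change == 0))
})

test_that("the importance table covers all 22 blocks per learner", {
  d <- coarse_dataset(seed = 11, step = 25)
  specs <- list(LASSO = learner_spec("LASSO", inner_folds = 3L, seed = 1),
                PLS = learner_spec("PLS", grid = list(ncomp = 4L),
                                   seed = 2))
  imp <- block_importance(d$X[1:70, ], d$y[1:70], specs,
                          repetitions = 2, seed = 4)
  expect_equal(nrow(imp$table), 22L * 2L)
  expect_setequal(unique(imp$table$block), LETTERS[1:22])
  expect_equal(dim(imp$raw), c(2L, 22L, 2L))
  expect_false(anyNA(imp$raw))
})

test_that("trait summaries reproduce the fold-change arithmetic", {
  rec <- tibble::tibble(
    genotype = c("a", "a", "b", "b"),
    vcmax = c(14.5, 200, 100, 344.6),
    j1800 = c(73.6, 150, 200, 362.0))
  s <- summarize_traits(rec)
  overall <- s[s$genotype == "Overall", ]
  expect_equal(round(overall$vcmax_fold, 1), 23.8)
  expect_equal(round(overall$j_fold, 1), 4.9)
  expect_equal(overall$n, 4L)
})

test_that("overall mean is the sample-size-weighted mean of genotypes", {
  tr <- simulate_traits(seed = 12)
  s <- summarize_traits(tr)
  per <- s[s$genotype != "Overall", ]
  weighted <- sum(per$n * per$vcmax_mean) / sum(per$n)
  expect_equal(s$vcmax_mean[s$genotype == "Overall"], weighted)
  expect_error(summarize_traits(tibble::tibble(genotype = "a",
                                               vcmax = -5)),
               "non-positive")
})

test_that("roster arithmetic matches the emulated trial's statistics", {
  rs <- roster_summary(tobacco_genotypes())
  expect_equal(rs$n, 212L)
  expect_equal(rs$n_j, 179L)
  expect_equal(round(rs$vcmax_fold, 1), 23.8)
  expect_lt(abs(rs$vcmax_weighted_mean - 175.5), 0.1)
})
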