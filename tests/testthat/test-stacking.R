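test_that("splits partition the samples at the 9:1 ratio", {
  ids <- sprintf("s%03d", 1:212)
  splits <- make_splits(ids, repeats = 10, seed = 1)
  expect_length(splits, 10L)
  for (s in splits) {
    expect_true(length(s$test_ids) %in% c(21L, 22L))
    expect_length(intersect(s$train_ids, s$test_ids), 0L)
    expect_setequal(c(s$train_ids, s$test_ids), ids)
  }
  expect_identical(splits, make_splits(ids, repeats = 10, seed = 1))
  expect_false(identical(splits, make_splits(ids, repeats = 10, seed = 2)))
  expect_error(make_splits(ids[1:10]), "at least 20")
  tab <- splits_to_table(splits)
  expect_equal(nrow(tab), 2120L)
})

test_that("the OOS matrix covers every training sample once per learner", {
  d <- coarse_dataset(seed = 1, step = 25)
  idx <- 1:60
  oos <- build_oos_matrix(d$X[idx, ], d$y[idx], fast_specs(), folds = 5,
                          seed = 3)
  expect_equal(dim(oos), c(60L, 2L))
  expect_false(anyNA(oos))
  expect_equal(rownames(oos), rownames(d$X[idx, ]))
})

test_that("OOS entries of a mean learner equal the other folds' mean", {
  d <- coarse_dataset(seed = 1, step = 25)
  idx <- 1:40
  specs <- list(MEAN = learner_spec("MEAN", seed = 1))
  oos <- build_oos_matrix(d$X[idx, ], d$y[idx], specs, folds = 4, seed = 9)
  folds <- attr(oos, "folds")
  for (f in unique(folds)) {
    oracle <- mean(d$y[idx][folds != f])  # brute-force per-fold mean
    expect_equal(unname(oos[folds == f, "MEAN"]),
                 rep(oracle, sum(folds == f)))
  }
})

test_that("poisoning one label never leaks into that sample's own row", {
  d <- coarse_dataset(seed = 2, step = 25)
  idx <- 1:60
  y <- d$y[idx]
  oos1 <- build_oos_matrix(d$X[idx, ], y, fast_specs(), folds = 5,
                           seed = 7)
  y_poison <- y
  y_poison[17] <- y[17] + 1000
  oos2 <- build_oos_matrix(d$X[idx, ], y_poison, fast_specs(), folds = 5,
                           seed = 7)
  # the poisoned sample's own out-of-fold predictions are untouched ...
  expect_identical(oos1[17, ], oos2[17, ])
  # ... and samples in its fold are untouched too (same training data),
  # while other folds' models saw the poisoned label and moved
  folds <- attr(oos1, "folds")
  same_fold <- folds == folds[17]
  expect_identical(oos1[same_fold, ], oos2[same_fold, ])
  expect_gt(max(abs(oos1[!same_fold, ] - oos2[!same_fold, ])), 1e-6)
})

test_that("a perfect level-1 predictor dominates the stack", {
  d <- coarse_dataset(seed = 3, step = 25)
  te <- seq(2, 212, by = 17)  # scattered across genotypes
  tr <- setdiff(1:212, te)
  y <- d$y
  perfect <- learner_spec("CUSTOM",
    fit = function(X, y) list(y = y, ids = rownames(X)),
    predict = function(state, X) {
      # oracle lookup by sample id: stands in for a learner whose
      # out-of-fold predictions equal the truth
      truth <- stats::setNames(d$y[rownames(X)], rownames(X))
      unname(truth)
    }, seed = 1)
  noise1 <- learner_spec("CUSTOM", fit = function(X, y) NULL,
    predict = function(state, X) 100 + 50 * sin(rowSums(X)), seed = 2)
  noise2 <- learner_spec("CUSTOM", fit = function(X, y) NULL,
    predict = function(state, X) 150 + 40 * cos(rowSums(X^2)), seed = 3)
  st <- fit_stack(d$X[tr, ], y[tr],
                  list(PERFECT = perfect, N1 = noise1, N2 = noise2),
                  folds = 5, seed = 3)
  pr <- predict_stack(st, d$X[te, ])
  expect_gte(r_squared(y[te], pr), 0.99)
  w <- st$level2_coefficients
  expect_gt(w[["PERFECT"]], 0.9)
})

test_that("an anti-correlated predictor receives a negative weight", {
  d <- coarse_dataset(seed = 4, step = 25)
  tr <- 1:200
  y <- d$y
  anti <- learner_spec("CUSTOM", fit = function(X, y) NULL,
    predict = function(state, X) {
      truth <- d$y[rownames(X)]
      unname(-truth + stats::rnorm(length(truth), 0, 5))
    }, seed = 5)
  st <- fit_stack(d$X[tr, ], y[tr],
                  c(fast_specs(), list(ANTI = anti)), folds = 5, seed = 5)
  expect_lt(st$level2_coefficients[["ANTI"]], 0)
})

test_that("identical learner columns collapse to the univariate LASSO", {
  d <- coarse_dataset(seed = 5, step = 25)
  tr <- 1:80
  same <- function(sd) learner_spec("CUSTOM", fit = function(X, y) NULL,
    predict = function(state, X) unname(d$y[rownames(X)] +
                                          10 * sin(rowSums(X))), seed = sd)
  st <- fit_stack(d$X[tr, ], d$y[tr],
                  list(A = same(1), B = same(2), C = same(3)),
                  folds = 5, seed = 11)
  x <- st$oos_matrix[, 1]
  y <- d$y[tr]
  expect_equal(st$oos_matrix[, 2], x)
  # univariate LASSO with intercept at the chosen penalty, closed form:
  # beta = S(cov_n(x,y), lambda) / var_n(x) on centered data
  xc <- x - mean(x); yc <- y - mean(y)
  rho <- mean(xc * yc); lam <- st$level2_penalty
  beta <- sign(rho) * max(abs(rho) - lam, 0) / mean(xc^2)
  fitted_oracle <- mean(y) + beta * xc
  expect_lt(max(abs(st$oos_fitted - fitted_oracle)), 1e-6)
  expect_equal(sum(st$level2_coefficients), beta, tolerance = 1e-6)
})

test_that("stack predictions are the affine combination of the learners", {
  d <- coarse_dataset(seed = 6, step = 25)
  tr <- 1:60; te <- 61:80
  st <- fit_stack(d$X[tr, ], d$y[tr], fast_specs(), folds = 5, seed = 2)
  pr <- predict_stack(st, d$X[te, ], level1 = TRUE)
  manual <- st$level2_intercept +
    as.numeric(pr$level1 %*% st$level2_coefficients)
  expect_equal(unname(pr$stack), manual)
  # zero weights -> constant intercept
  st0 <- st; st0$level2_coefficients[] <- 0
  expect_equal(unname(predict_stack(st0, d$X[te, ])),
               rep(st$level2_intercept, 20))
  # one-hot weights -> that learner's predictions
  st1 <- st; st1$level2_coefficients[] <- c(1, 0)
  st1$level2_intercept <- 0
  expect_equal(unname(predict_stack(st1, d$X[te, ])),
               unname(pr$level1[, 1]))
  # perturbing one learner's output moves predictions by weight * delta
  st2 <- st
  st2$level1$PLS <- st$level1$PLS
  delta <- 3.7
  bump <- matrix(c(0, delta), nrow(pr$level1), 2, byrow = TRUE)
  pr2 <- st$level2_intercept +
    as.numeric((pr$level1 + bump) %*% st$level2_coefficients)
  expect_equal(pr2 - manual,
               rep(st$level2_coefficients[["PLS"]] * delta, 20))
})

test_that("level-2 coefficients table has one weight per learner", {
  d <- coarse_dataset(seed = 7, step = 25)
  st <- fit_stack(d$X[1:60, ], d$y[1:60], fast_specs(), folds = 5,
                  seed = 4)
  tab <- level2_coefficients(st)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$learner, c("LASSO", "PLS"))
  expect_type(attr(tab, "intercept"), "double")
})

test_that("a pure-noise learner column is shrunk to near zero", {
  withr::with_seed(11, {
    n <- 500
    y <- stats::rnorm(n, 150, 60)
    oos <- cbind(GOOD = y + stats::rnorm(n, 0, 15),
                 NOISE = stats::rnorm(n, 150, 60))
  })
  l2 <- photostack:::fit_level2_lasso(oos, y, seed = 11)
  expect_lt(abs(l2$weights[["NOISE"]]), 0.05)
  expect_gt(l2$weights[["GOOD"]], 0.8)
})

test_that("stack models survive a JSON round trip bit-identically", {
  d <- coarse_dataset(seed = 8, step = 25)
  tr <- 1:60; te <- 61:90
  st <- fit_stack(d$X[tr, ], d$y[tr], fast_specs(), folds = 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_stack_model(st, path)
  st2 <- load_stack_model(path)
  expect_identical(predict_stack(st, d$X[te, ]),
                   predict_stack(st2, d$X[te, ]))
  expect_equal(st2$level2_coefficients, st$level2_coefficients)
})
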