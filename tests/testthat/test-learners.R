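test_that("all six learners recover a linear trait from correlated bands", {
  d <- linear_band_dataset(seed = 7)
  tr <- 1:70; te <- 71:100
  r2 <- vapply(c("ANN", "SVM", "LASSO", "RF", "GP", "PLS"), function(k) {
    sp <- learner_spec(k, grid = default_grid(k, reduced = TRUE),
                       inner_folds = 5L, seed = 7)
    m <- fit_learner(sp, d$X[tr, ], d$y[tr])
    r_squared(d$y[te], predict_learner(m, d$X[te, ]))
  }, numeric(1))
  expect_gte(r2[["LASSO"]], 0.95)
  expect_gte(r2[["PLS"]], 0.95)
  expect_gte(r2[["GP"]], 0.95)
  expect_gte(r2[["SVM"]], 0.95)
  expect_gte(r2[["RF"]], 0.7)
  expect_gte(r2[["ANN"]], 0.5)
})

test_that("fitting is deterministic given the spec seed", {
  d <- linear_band_dataset(seed = 3, n = 60, p = 30)
  for (k in c("ANN", "RF", "GP")) {
    grid <- switch(k,
                   ANN = list(size = c(3L, 5L), decay = c(1e-3, 1e-2),
                              maxit = 40L),
                   RF = list(num_trees = 80L, mtry = c("p10", "sqrt")),
                   GP = list(restarts = 2L))
    sp <- learner_spec(k, grid = grid, inner_folds = 3L, seed = 11)
    m1 <- fit_learner(sp, d$X, d$y)
    m2 <- fit_learner(sp, d$X, d$y)
    expect_identical(m1$chosen, m2$chosen)
    expect_identical(predict_learner(m1, d$X), predict_learner(m2, d$X))
  }
})

test_that("degenerate inputs are rejected before fitting", {
  d <- linear_band_dataset(seed = 3, n = 40, p = 10)
  sp <- learner_spec("LASSO", seed = 1)
  expect_error(fit_learner(sp, d$X, rep(1, 40)), "constant y")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(fit_learner(sp, Xna, d$y), "NaN|NA")
  sp2 <- learner_spec("PLS", inner_folds = 30L, seed = 1)
  expect_error(fit_learner(sp2, d$X, d$y), "inner_folds")
})

test_that("full-rank PLS equals ordinary least squares", {
  withr::with_seed(21, {
    X <- matrix(stats::rnorm(50 * 10), 50, 10,
                dimnames = list(NULL, 1:10))
    y <- stats::rnorm(50)
  })
  m <- fit_learner(learner_spec("PLS", grid = list(ncomp = 10L), seed = 1),
                   X, y)
  ols <- as.numeric(cbind(1, X) %*% stats::coef(stats::lm(y ~ X)))
  expect_lt(max(abs(predict_learner(m, X) - ols)), 1e-6)
})

test_that("SIMPLS agrees with an independent PLS implementation", {
  withr::with_seed(8, {
    X <- matrix(stats::rnorm(40 * 15), 40, 15,
                dimnames = list(NULL, 1:15))
    y <- as.numeric(X[, 1:5] %*% stats::runif(5, 0.5, 1)) +
      stats::rnorm(40, sd = 0.2)
  })
  m <- fit_learner(learner_spec("PLS", grid = list(ncomp = 4L), seed = 1),
                   X, y)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  ref_pred <- predict(ref, X)$predict[, 1, 4]
  expect_lt(max(abs(predict_learner(m, X) - ref_pred)), 1e-6)
})

test_that("GP predictions match the closed-form posterior mean", {
  withr::with_seed(13, {
    X <- matrix(stats::rnorm(35 * 8), 35, 8, dimnames = list(NULL, 1:8))
    y <- as.numeric(sin(X[, 1]) + 0.5 * X[, 2]) + stats::rnorm(35, sd = 0.1)
    Xnew <- matrix(stats::rnorm(10 * 8), 10, 8,
                   dimnames = list(NULL, 1:8))
  })
  m <- fit_learner(learner_spec("GP", grid = list(restarts = 2L),
                                seed = 5), X, y)
  h <- m$chosen
  # independent oracle: k*' (K + sn2 I)^-1 y on the standardized scale
  K <- h$sf2 * exp(-as.matrix(stats::dist(X))^2 / (2 * h$ell2))
  diag(K) <- diag(K) + h$sn2 + 1e-8
  d2 <- outer(rowSums(Xnew^2), rowSums(X^2), "+") - 2 * Xnew %*% t(X)
  Ks <- h$sf2 * exp(-pmax(d2, 0) / (2 * h$ell2))
  yc <- (y - mean(y)) / stats::sd(y)
  oracle <- mean(y) + stats::sd(y) * as.numeric(Ks %*% solve(K, yc))
  expect_lt(max(abs(predict_learner(m, Xnew) - oracle)), 1e-6)
})

test_that("predictions are row-independent and band-checked", {
  d <- linear_band_dataset(seed = 9, n = 50, p = 20)
  m <- fit_learner(learner_spec("SVM",
                                grid = list(cost = 10, gamma_mult = 1),
                                seed = 2), d$X, d$y)
  pr <- predict_learner(m, d$X)
  expect_length(pr, 50L)
  dup <- d$X[c(1, 1, 2), ]
  pr_dup <- predict_learner(m, dup)
  expect_equal(pr_dup[1], pr_dup[2])
  expect_error(predict_learner(m, d$X[, -1]), "missing band")
})

test_that("inner-CV tuning never scores a candidate on its training fold", {
  d <- linear_band_dataset(seed = 2, n = 30, p = 5)
  log_train <- list(); log_test <- list()
  fit_fun <- function(X, y, cand, s) {
    log_train[[length(log_train) + 1]] <<- rownames(X)
    list(mean = mean(y))
  }
  pred_fun <- function(fit, X) {
    log_test[[length(log_test) + 1]] <<- rownames(X)
    rep(fit$mean, nrow(X))
  }
  photostack:::tune_by_cv(list(list(a = 1), list(a = 2)), fit_fun,
                          pred_fun, d$X, d$y, k = 3L, seed = 4)
  for (i in seq_along(log_train)) {
    expect_length(intersect(log_train[[i]], log_test[[i]]), 0L)
    expect_setequal(c(log_train[[i]], log_test[[i]]), rownames(d$X))
  }
})

test_that("fitted learners round-trip through their JSON envelope", {
  d <- linear_band_dataset(seed = 17, n = 60, p = 25)
  for (k in c("LASSO", "GP")) {
    m <- fit_learner(learner_spec(k, grid = default_grid(k, TRUE),
                                  inner_folds = 3L, seed = 3), d$X, d$y)
    path <- withr::local_tempfile(fileext = ".json")
    save_learner(m, path)
    m2 <- load_learner(path)
    expect_identical(predict_learner(m2, d$X), predict_learner(m, d$X))
    expect_equal(m2$chosen, m$chosen)
  }
})
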