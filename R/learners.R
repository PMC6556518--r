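# The six level-1 regression learners behind one contract.
# LASSO (glmnet), ANN (nnet), SVM-RBF (e1071) and RF (ranger) wrap
# installed packages; PLS (SIMPLS) and the exact RBF-kernel Gaussian
# process with marginal-likelihood tuning are implemented here. Each
# learner carries its hyperparameter-selection rule: inner-CV RMSE for
# ANN/SVM/LASSO/PLS, out-of-bag error for RF, and Type-II maximum
# likelihood for the GP.

LEARNER_KINDS <- c("ANN", "SVM", "LASSO", "RF", "GP", "PLS")

#' Specify a level-1 learner
#'
#' @param kind One of `"ANN"`, `"SVM"`, `"LASSO"`, `"RF"`, `"GP"`,
#'   `"PLS"`, or the utility kinds `"MEAN"` (predicts the training mean)
#'   and `"CUSTOM"` (user-supplied `fit`/`predict` functions).
#' @param grid Kind-specific hyperparameter search space; `NULL` uses
#'   [default_grid()].
#' @param inner_folds Folds for inner-CV hyperparameter tuning.
#' @param seed Integer seed governing all randomness in fitting.
#' @param fit,predict For `kind = "CUSTOM"`: `fit(X, y) -> state` and
#'   `predict(state, X) -> numeric`.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind, grid = NULL, inner_folds = 5L, seed = 1L,
                         fit = NULL, predict = NULL) {
  kind <- match.arg(kind, c(LEARNER_KINDS, "MEAN", "CUSTOM"))
  if (kind == "CUSTOM" && (is.null(fit) || is.null(predict))) {
    stop("CUSTOM learners need fit and predict functions")
  }
  if (is.null(grid) && kind %in% LEARNER_KINDS) grid <- default_grid(kind)
  structure(list(kind = kind, grid = grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), fit = fit, predict = predict),
            class = "learner_spec")
}

#' Default hyperparameter search spaces
#'
#' The tuning *rules* are fixed per learner (CV-RMSE, OOB error, marginal
#' likelihood); the grids themselves are package defaults, exposed so
#' analyses can trade search breadth for runtime.
#'
#' @param kind Learner kind.
#' @param reduced Use the compact grids intended for the repeated
#'   benchmark protocols (fewer candidates, same rules).
#' @return A list describing the search space.
#' @export
default_grid <- function(kind, reduced = FALSE) {
  switch(kind,
    ANN = if (reduced) {
      list(size = c(3L, 5L), decay = c(1e-3, 1e-2), maxit = 150L,
           rank = 15L, averages = 3L)
    } else {
      list(size = c(5L, 10L, 20L, 50L), decay = c(1e-4, 1e-3, 1e-2),
           maxit = 300L, rank = 30L, averages = 5L)
    },
    SVM = if (reduced) {
      list(cost = 100, gamma_mult = 1)
    } else {
      list(cost = c(0.1, 1, 10, 100, 1000), gamma_mult = c(0.5, 1, 2))
    },
    LASSO = list(nlambda = 100L),
    RF = if (reduced) {
      list(num_trees = 150L, mtry = "sqrt")
    } else {
      list(num_trees = 500L, mtry = c("p10", "sqrt", "p3"))
    },
    GP = list(restarts = if (reduced) 1L else 5L),
    PLS = list(ncomp = if (reduced) 1:10 else 1:30),
    stop("no default grid for kind ", kind)
  )
}

#' The six default learner specs
#'
#' @param inner_folds Inner tuning folds.
#' @param seed Base seed; each learner gets a distinct derived seed.
#' @param reduced Use compact search grids (see [default_grid()]).
#' @return Named list of six [learner_spec()] objects.
#' @export
default_learner_specs <- function(inner_folds = 5L, seed = 1L,
                                  reduced = TRUE) {
  specs <- lapply(seq_along(LEARNER_KINDS), function(i) {
    learner_spec(LEARNER_KINDS[i],
                 grid = default_grid(LEARNER_KINDS[i], reduced = reduced),
                 inner_folds = inner_folds, seed = seed + 17L * i)
  })
  names(specs) <- LEARNER_KINDS
  specs
}

#' Compact stability-oriented learner specs for ablation studies
#'
#' Fixed single-candidate settings chosen so refit-to-refit variation
#' stays well below the effects a band-ablation study measures: an
#' averaged-net ANN on a rank-2 supervised compression, 300-tree RF,
#' CV-chosen PLS components, and the benchmark LASSO/SVM/GP settings.
#'
#' @param seed Base seed; each learner gets a distinct derived seed.
#' @return Named list of six [learner_spec()] objects.
#' @export
ablation_learner_specs <- function(seed = 1L) {
  list(
    ANN = learner_spec("ANN", grid = list(size = 4L, decay = 1e-2,
                                          maxit = 300L, rank = 2L,
                                          averages = 5L), seed = seed),
    SVM = learner_spec("SVM", grid = list(cost = 10, gamma_mult = 1),
                       seed = seed + 1L),
    LASSO = learner_spec("LASSO", inner_folds = 3L, seed = seed + 2L),
    RF = learner_spec("RF", grid = list(num_trees = 300L, mtry = "sqrt"),
                      seed = seed + 3L),
    GP = learner_spec("GP", grid = list(restarts = 1L), seed = seed + 4L),
    PLS = learner_spec("PLS", grid = list(ncomp = 1:10), inner_folds = 3L,
                       seed = seed + 5L)
  )
}

make_cv_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# median-heuristic RBF bandwidth: median pairwise squared distance over a
# subsample of rows
median_sq_dist <- function(X, max_rows = 120L, seed = 1L) {
  idx <- if (nrow(X) > max_rows) {
    with_seed(seed, sample(nrow(X), max_rows))
  } else {
    seq_len(nrow(X))
  }
  d2 <- stats::dist(X[idx, , drop = FALSE])^2
  stats::median(as.numeric(d2))
}

validate_xy <- function(spec, X, y) {
  if (!is.matrix(X) || is.null(colnames(X))) {
    stop("X must be a matrix with band column names")
  }
  if (anyNA(X) || any(!is.finite(X))) stop("X contains NaN/NA values")
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  if (stats::sd(y) == 0) stop("constant y: fit rejected")
  if (spec$kind %in% c("ANN", "SVM", "PLS") &&
      nrow(X) < 2L * spec$inner_folds) {
    stop("need at least 2 x inner_folds samples for CV tuning")
  }
  invisible(TRUE)
}

# Generic inner-CV RMSE tuner over a list of candidate settings. Each
# candidate is fit on k-1 folds and scored on the held fold; ties go to
# the earlier (simpler) candidate.
tune_by_cv <- function(candidates, fit_fun, pred_fun, X, y, k, seed) {
  if (length(candidates) == 1L) {
    return(list(best = candidates[[1L]], rmse = NA_real_, all = NA_real_))
  }
  folds <- make_cv_folds(nrow(X), k, seed)
  rmses <- vapply(seq_along(candidates), function(ci) {
    sse <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_fun(X[tr, , drop = FALSE], y[tr], candidates[[ci]],
                     seed + 1000L * ci + f)
      pred <- pred_fun(fit, X[!tr, , drop = FALSE])
      sse <- sse + sum((y[!tr] - pred)^2)
    }
    sqrt(sse / length(y))
  }, numeric(1))
  list(best = candidates[[which.min(rmses)]], rmse = min(rmses),
       all = rmses)
}

fitted_learner <- function(spec, chosen, state, summary, bands) {
  structure(list(spec = spec, kind = spec$kind, chosen = chosen,
                 state = state, training_summary = summary, bands = bands),
            class = "fitted_learner")
}

#' Fit one level-1 learner
#'
#' Hyperparameters are selected by the learner's tuning rule (inner-CV
#' RMSE; OOB error for RF; marginal likelihood for GP), then the final
#' model is refit on all of `(X, y)` at the chosen setting. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [learner_spec()].
#' @param X Standardized predictor matrix (samples x bands).
#' @param y Trait vector.
#' @return An object of class `fitted_learner`.
#' @export
fit_learner <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  validate_xy(spec, X, y)
  switch(spec$kind,
    ANN = fit_ann(spec, X, y),
    SVM = fit_svm(spec, X, y),
    LASSO = fit_lasso(spec, X, y),
    RF = fit_rf(spec, X, y),
    GP = fit_gp(spec, X, y),
    PLS = fit_pls(spec, X, y),
    MEAN = fitted_learner(spec, list(), list(mean = mean(y)),
                          mean(y), colnames(X)),
    CUSTOM = fitted_learner(spec, list(), spec$fit(X, y), NA_real_,
                            colnames(X))
  )
}

#' Predict from a fitted learner
#'
#' @param model A [fit_learner()] result.
#' @param X Standardized matrix containing the training bands.
#' @return One finite prediction per row of `X`.
#' @export
predict_learner <- function(model, X) {
  stopifnot(inherits(model, "fitted_learner"))
  missing <- setdiff(model$bands, colnames(X))
  if (length(missing) > 0L) {
    stop("X is missing band(s) the model was trained on: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  X <- X[, model$bands, drop = FALSE]
  pred <- switch(model$kind,
    ANN = predict_ann_state(model$state, X),
    SVM = as.numeric(stats::predict(model$state$svm, X)),
    LASSO = as.numeric(stats::predict(model$state$glmnet, X,
                                      s = model$chosen$lambda)),
    RF = stats::predict(model$state$rf, data = X,
                        num.threads = 1L)$predictions,
    GP = predict_gp_state(model$state, X),
    PLS = predict_simpls(model$state, X),
    MEAN = rep(model$state$mean, nrow(X)),
    CUSTOM = as.numeric(model$spec$predict(model$state, X))
  )
  if (length(pred) != nrow(X) || any(!is.finite(pred))) {
    stop("learner ", model$kind, " produced non-finite predictions")
  }
  names(pred) <- rownames(X)
  pred
}

# --- ANN: single-hidden-layer back-propagation network on a frozen
# --- supervised linear input compression (PLS latent scores of the
# --- standardized bands). A net fed thousands of collinear bands is
# --- numerically wasteful (the weight count, and the quadratic-cost
# --- BFGS updates behind nnet, scale with the band count) and its
# --- unsupervised compressions rotate with uninformative bands; the
# --- signal-anchored PLS directions are stable. The compression is
# --- refit inside every tuning fold so inner CV stays leakage-free,
# --- and several random-init nets are averaged because single
# --- back-propagation fits are nonconvex and noisy.

ann_compress <- function(X, y, k) {
  pls <- simpls(X, y, k)
  S <- sweep(X, 2L, pls$xbar) %*% pls$R
  ssd <- apply(S, 2L, stats::sd)
  ssd[ssd < 1e-12] <- 1
  list(xbar = pls$xbar, R = pls$R, score_sd = ssd,
       scores = sweep(S, 2L, ssd, "/"))
}

ann_project <- function(comp, X) {
  sweep(sweep(X, 2L, comp$xbar) %*% comp$R, 2L, comp$score_sd, "/")
}

fit_ann <- function(spec, X, y) {
  g <- spec$grid
  k <- min(g$rank %||% 15L, nrow(X) - 2L, ncol(X))
  # train on the standardized response so near-zero initial weights
  # start close to the mean prediction and decay acts on a sane scale
  my <- mean(y); sy <- stats::sd(y)
  yz <- (y - my) / sy
  cands <- expand.grid(size = g$size, decay = g$decay)
  cands <- lapply(seq_len(nrow(cands)), function(i) as.list(cands[i, ]))
  net_one <- function(Str, ytr, cand, sd_i) {
    with_seed(sd_i,
      nnet::nnet(x = Str, y = ytr, size = cand$size, decay = cand$decay,
                 linout = TRUE, maxit = g$maxit, trace = FALSE,
                 MaxNWts = 20000L))
  }
  fit_one <- function(Xtr, ytr, cand, sd_i) {
    comp <- ann_compress(Xtr, ytr, k)
    list(comp = comp, net = net_one(comp$scores, ytr, cand, sd_i))
  }
  pred_one <- function(fit, Xte) {
    as.numeric(stats::predict(fit$net, ann_project(fit$comp, Xte)))
  }
  tuned <- tune_by_cv(cands, fit_one, pred_one, X, yz,
                      spec$inner_folds, spec$seed)
  comp <- ann_compress(X, yz, k)
  n_nets <- max(1L, g$averages %||% 3L)
  nets <- lapply(seq_len(n_nets), function(i) {
    net_one(comp$scores, yz, tuned$best, spec$seed + 7919L * i)
  })
  fitted_learner(spec, tuned$best,
                 list(nets = nets, comp = comp, y_mean = my, y_sd = sy),
                 tuned$rmse, colnames(X))
}

predict_ann_state <- function(state, X) {
  Sz <- ann_project(state$comp, X)
  preds <- vapply(state$nets,
                  function(net) as.numeric(stats::predict(net, Sz)),
                  numeric(nrow(Sz)))
  if (nrow(Sz) == 1L) preds <- matrix(preds, nrow = 1L)
  state$y_mean + state$y_sd * rowMeans(preds)
}

# --- SVM with RBF kernel ------------------------------------------------

fit_svm <- function(spec, X, y) {
  g <- spec$grid
  gamma0 <- 1 / max(median_sq_dist(X, seed = spec$seed), 1e-8)
  cands <- expand.grid(cost = g$cost, gamma = gamma0 * g$gamma_mult)
  cands <- lapply(seq_len(nrow(cands)), function(i) as.list(cands[i, ]))
  fit_one <- function(Xtr, ytr, cand, sd_i) {
    e1071::svm(x = Xtr, y = ytr, type = "eps-regression",
               kernel = "radial", cost = cand$cost, gamma = cand$gamma,
               scale = FALSE)
  }
  tuned <- tune_by_cv(cands, fit_one,
                      function(fit, Xte) as.numeric(stats::predict(fit, Xte)),
                      X, y, spec$inner_folds, spec$seed)
  mod <- fit_one(X, y, tuned$best, spec$seed)
  fitted_learner(spec, tuned$best, list(svm = mod), tuned$rmse,
                 colnames(X))
}

# --- LASSO: glmnet path with CV-chosen penalty --------------------------

fit_lasso <- function(spec, X, y) {
  foldid <- make_cv_folds(nrow(X), max(spec$inner_folds, 3L), spec$seed)
  cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                             nlambda = spec$grid$nlambda,
                             standardize = FALSE)
  # ties toward the larger penalty (sparser model)
  lam <- max(cvfit$lambda[cvfit$cvm <= min(cvfit$cvm) + 1e-12])
  fitted_learner(spec, list(lambda = lam),
                 list(glmnet = cvfit$glmnet.fit),
                 sqrt(min(cvfit$cvm)), colnames(X))
}

# --- Random forest: OOB-error-tuned mtry --------------------------------

fit_rf <- function(spec, X, y) {
  g <- spec$grid
  p <- ncol(X)
  mtry_val <- function(code) {
    as.integer(switch(code, p10 = max(1, floor(p / 10)),
                      sqrt = max(1, floor(sqrt(p))),
                      p3 = max(1, floor(p / 3)),
                      stop("unknown mtry code ", code)))
  }
  cand <- vapply(g$mtry, mtry_val, integer(1))
  fits <- lapply(seq_along(cand), function(i) {
    ranger::ranger(y = y, x = X, num.trees = g$num_trees,
                   mtry = min(cand[i], p), seed = spec$seed + i,
                   num.threads = 1L)
  })
  oob <- vapply(fits, function(f) f$prediction.error, numeric(1))
  best <- which.min(oob)
  fitted_learner(spec, list(mtry = cand[best], num_trees = g$num_trees),
                 list(rf = fits[[best]]), sqrt(oob[best]), colnames(X))
}

# --- Gaussian process: exact GP, RBF + noise kernel, hyperparameters by
# --- Type-II maximum likelihood (L-BFGS-B with random restarts) ---------

gp_nll <- function(theta, D2, yc) {
  n <- length(yc)
  ell2 <- exp(theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
  K <- sf2 * exp(-D2 / (2 * ell2))
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
  as.numeric(0.5 * crossprod(yc, alpha) + sum(log(diag(ch))) +
               0.5 * n * log(2 * pi))
}

fit_gp <- function(spec, X, y) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  my <- mean(y); sy <- stats::sd(y)
  yc <- (y - my) / sy
  med <- max(stats::median(D2[upper.tri(D2)]), 1e-8)
  base_init <- c(log(med), 0, log(0.1))
  inits <- with_seed(spec$seed, {
    jit <- matrix(stats::rnorm(3L * max(spec$grid$restarts - 1L, 0L), 0, 1),
                  ncol = 3L)
    rbind(base_init,
          sweep(jit, 2L, base_init, "+"))
  })
  best <- NULL
  for (i in seq_len(nrow(inits))) {
    opt <- tryCatch(
      stats::optim(inits[i, ], gp_nll, D2 = D2, yc = yc,
                   method = "L-BFGS-B",
                   lower = c(log(med) - 8, -8, log(1e-5)),
                   upper = c(log(med) + 8, 6, 4),
                   control = list(maxit = 100L)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("GP marginal-likelihood optimization failed")
  theta <- best$par
  ell2 <- exp(theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
  K <- sf2 * exp(-D2 / (2 * ell2))
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, yc, transpose = TRUE))
  state <- list(Xtrain = X, row_sq = rowSums(X^2), ell2 = ell2, sf2 = sf2,
                sn2 = sn2, alpha = alpha, my = my, sy = sy)
  fitted_learner(spec, list(ell2 = ell2, sf2 = sf2, sn2 = sn2), state,
                 best$value, colnames(X))
}

predict_gp_state <- function(state, X) {
  cross <- outer(rowSums(X^2), state$row_sq, "+") -
    2 * X %*% t(state$Xtrain)
  cross[cross < 0] <- 0
  Ks <- state$sf2 * exp(-cross / (2 * state$ell2))
  as.numeric(state$my + state$sy * (Ks %*% state$alpha))
}

# --- PLS: SIMPLS with CV-chosen number of latent variables --------------

# SIMPLS (de Jong 1993) for a univariate response. Returns the weight
# matrix R and loadings Q so predictions at any number of components
# a <= ncomp come from the cumulative sums of (X - xbar) R diag(Q).
simpls <- function(X, y, ncomp) {
  xbar <- colMeans(X); ybar <- mean(y)
  X0 <- sweep(X, 2L, xbar); y0 <- y - ybar
  p <- ncol(X)
  ncomp <- min(ncomp, nrow(X) - 1L, p)
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  S <- crossprod(X0, y0)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t_scores <- X0 %*% r
    nt <- sqrt(sum(t_scores^2))
    if (!is.finite(nt) || nt < 1e-12) break
    t_scores <- t_scores / nt
    r <- r / nt
    p_load <- crossprod(X0, t_scores)
    q_load <- as.numeric(crossprod(y0, t_scores))
    v <- p_load
    if (a > 1L) {
      Vprev <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vprev %*% crossprod(Vprev, p_load)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v; Q[a] <- q_load
    a_used <- a
  }
  list(xbar = xbar, ybar = ybar,
       R = R[, seq_len(a_used), drop = FALSE],
       Q = Q[seq_len(a_used)], ncomp = a_used)
}

# predictions at every component count 1..fit$ncomp (matrix n x ncomp)
simpls_path <- function(fit, X) {
  X0 <- sweep(X, 2L, fit$xbar)
  Tm <- X0 %*% fit$R
  contrib <- sweep(Tm, 2L, fit$Q, "*")
  cum <- if (ncol(contrib) == 1L) contrib
         else t(apply(contrib, 1L, cumsum))
  fit$ybar + cum
}

predict_simpls <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  X0 <- sweep(X, 2L, fit$xbar)
  beta <- fit$R[, seq_len(ncomp), drop = FALSE] %*%
    fit$Q[seq_len(ncomp)]
  as.numeric(fit$ybar + X0 %*% beta)
}

fit_pls <- function(spec, X, y) {
  ncands <- spec$grid$ncomp
  maxc <- min(max(ncands), nrow(X) - 2L, ncol(X))
  ncands <- ncands[ncands <= maxc]
  if (length(ncands) == 0L) ncands <- 1L
  if (length(ncands) > 1L) {
    folds <- make_cv_folds(nrow(X), spec$inner_folds, spec$seed)
    sse <- numeric(length(ncands))
    for (f in seq_len(spec$inner_folds)) {
      tr <- folds != f
      fit <- simpls(X[tr, , drop = FALSE], y[tr], max(ncands))
      path <- simpls_path(fit, X[!tr, , drop = FALSE])
      for (ci in seq_along(ncands)) {
        a <- min(ncands[ci], fit$ncomp)
        sse[ci] <- sse[ci] + sum((y[!tr] - path[, a])^2)
      }
    }
    best <- ncands[which.min(sse)]
    cv_rmse <- sqrt(min(sse) / length(y))
  } else {
    best <- ncands
    cv_rmse <- NA_real_
  }
  fit <- simpls(X, y, best)
  fitted_learner(spec, list(ncomp = fit$ncomp), fit, cv_rmse, colnames(X))
}

#' @export
print.fitted_learner <- function(x, ...) {
  ch <- paste(names(x$chosen), vapply(x$chosen, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("fitted %s learner (%d bands)%s\n", x$kind, length(x$bands),
              if (nzchar(ch)) paste0("; chosen: ", ch) else ""))
  invisible(x)
}

#' Serialize a fitted learner to a JSON envelope
#'
#' The envelope carries the learner kind and chosen hyperparameters in
#' clear JSON plus a base64 blob of the serialized model state, so a
#' reloaded learner reproduces predictions bit-identically.
#'
#' @param model A [fit_learner()] result.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
save_learner <- function(model, path) {
  stopifnot(inherits(model, "fitted_learner"))
  envelope <- list(class = "fitted_learner", kind = model$kind,
                   chosen = model$chosen,
                   blob = jsonlite::base64_enc(serialize(model, NULL)))
  writeLines(jsonlite::toJSON(envelope, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Restore a fitted learner from its JSON envelope
#'
#' @param path File written by [save_learner()].
#' @return A `fitted_learner`.
#' @export
load_learner <- function(path) {
  env <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(env$class, "fitted_learner")) {
    stop("not a fitted_learner envelope: ", path)
  }
  unserialize(jsonlite::base64_dec(env$blob))
}
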