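# FvCB (Farquhar-von Caemmerer-Berry) C3 photosynthesis model:
# forward assimilation as the minimum of Rubisco-, RuBP-regeneration- and
# (optionally) TPU-limited rates, with chloroplastic CO2 Cc = Ci - A/gm
# resolved in closed form, and multi-start nonlinear least-squares fitting
# of A/Ci curves to recover Vc,max, J, Rd (and optionally TPU).

#' Rubisco kinetic constants
#'
#' Default values are the widely used tobacco constants at 25 degC
#' (Gamma* = 42.75 umol/mol, Kc = 404.9 umol/mol, Ko = 278.4 mmol/mol,
#' O = 210 mmol/mol). All are exposed because measured leaves at other
#' temperatures need other constants; no temperature response is applied.
#'
#' @param gamma_star CO2 compensation point in the absence of day
#'   respiration (umol mol^-1).
#' @param Kc Michaelis constant of Rubisco for CO2 (umol mol^-1).
#' @param Ko Michaelis constant of Rubisco for O2 (mmol mol^-1).
#' @param O Oxygen concentration (mmol mol^-1).
#' @return An object of class `kinetic_constants`.
#' @export
kinetic_constants <- function(gamma_star = 42.75, Kc = 404.9, Ko = 278.4,
                              O = 210) {
  vals <- c(gamma_star = gamma_star, Kc = Kc, Ko = Ko, O = O)
  if (!all(vapply(vals, is_number, logical(1))) || any(vals <= 0)) {
    stop("all kinetic constants must be finite and strictly positive")
  }
  structure(as.list(vals), class = "kinetic_constants")
}

#' FvCB model parameters for one leaf
#'
#' @param vcmax Maximum Rubisco carboxylation rate (umol m^-2 s^-1).
#' @param j Electron transport rate at measurement light, the J1800 of the
#'   measurement protocol (umol m^-2 s^-1).
#' @param rd Day respiration (umol m^-2 s^-1).
#' @param tpu Triose-phosphate utilization rate (umol m^-2 s^-1) or `NULL`
#'   to disable the TPU limitation (the default).
#' @param gm Mesophyll conductance (mol m^-2 s^-1 bar^-1); `Inf` makes
#'   Cc = Ci.
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(vcmax, j, rd = 0, tpu = NULL, gm = Inf) {
  if (!is_number(vcmax) || vcmax <= 0) stop("vcmax must be > 0")
  if (!is_number(j) || j <= 0) stop("j must be > 0")
  if (!is_number(rd) || rd < 0) stop("rd must be >= 0")
  if (!is.null(tpu) && (!is_number(tpu) || tpu <= 0)) {
    stop("tpu must be > 0 when present")
  }
  if (!is.numeric(gm) || length(gm) != 1L || is.na(gm) || gm <= 0) {
    stop("gm must be > 0 (possibly Inf)")
  }
  structure(list(vcmax = vcmax, j = j, rd = rd, tpu = tpu, gm = gm),
            class = "fvcb_params")
}

# Solve one limitation's quadratic in A for finite gm. The gross rate has
# the Michaelis form numerator*(Cc - gamma_star)/(den_a*Cc + den_b) and
# Cc = Ci - A/gm; substituting gives a*A^2 + b*A + c = 0 with a < 0, whose
# lower root is the physical assimilation rate.
solve_limitation <- function(numerator, den_a, den_b, rd, gm, gamma_star, ci,
                             label) {
  a <- -den_a / gm
  b <- (den_a * ci + den_b) + (numerator - den_a * rd) / gm
  cc <- rd * (den_a * ci + den_b) - numerator * (ci - gamma_star)
  disc <- b^2 - 4 * a * cc
  if (any(disc < 0)) {
    stop("no real solution for the ", label,
         "-limited rate; nonphysical parameter combination")
  }
  # lower root, in the cancellation-free form (a < 0, b > 0 here)
  2 * cc / (-b - sqrt(disc))
}

#' Net CO2 assimilation from the FvCB model
#'
#' Computes A = min(Ac, Aj, Ap) where Ac is the Rubisco-limited rate,
#' Aj the RuBP-regeneration-limited rate and Ap the TPU-limited rate
#' (included only when `params$tpu` is set). With finite mesophyll
#' conductance the chloroplastic CO2 drawdown Cc = Ci - A/gm is resolved
#' per limitation in closed form (each branch is a quadratic in A).
#'
#' @param params An [fvcb_params()] object.
#' @param kinetics A [kinetic_constants()] object.
#' @param ci Intercellular CO2 concentration(s), umol mol^-1 (vectorized).
#' @param details If `TRUE`, return a data frame with per-observation
#'   branch rates and the limiting state label.
#' @return Net assimilation (umol m^-2 s^-1), or a data frame when
#'   `details = TRUE`.
#' @export
forward_assimilation <- function(params, kinetics = kinetic_constants(),
                                 ci, details = FALSE) {
  stopifnot(inherits(params, "fvcb_params"),
            inherits(kinetics, "kinetic_constants"))
  if (!is.numeric(ci) || length(ci) < 1L || any(!is.finite(ci)) ||
      any(ci <= 0)) {
    stop("ci must be strictly positive and finite")
  }
  km <- kinetics$Kc * (1 + kinetics$O / kinetics$Ko)
  gs <- kinetics$gamma_star
  if (is.infinite(params$gm)) {
    ac <- params$vcmax * (ci - gs) / (ci + km) - params$rd
    aj <- params$j * (ci - gs) / (4 * ci + 8 * gs) - params$rd
  } else {
    ac <- solve_limitation(params$vcmax, 1, km, params$rd, params$gm, gs,
                           ci, "Rubisco")
    aj <- solve_limitation(params$j, 4, 8 * gs, params$rd, params$gm, gs,
                           ci, "RuBP")
  }
  branches <- cbind(Rubisco = ac, RuBP = aj)
  if (!is.null(params$tpu)) {
    branches <- cbind(branches, TPU = 3 * params$tpu - params$rd)
  }
  idx <- apply(branches, 1L, which.min)
  a <- branches[cbind(seq_along(ci), idx)]
  if (details) {
    out <- data.frame(ci = ci, a = a,
                      limitation = colnames(branches)[idx])
    out$ac <- ac
    out$aj <- aj
    if (!is.null(params$tpu)) out$ap <- 3 * params$tpu - params$rd
    return(out)
  }
  a
}

#' Construct an A/Ci curve
#'
#' @param sample_id Leaf identifier.
#' @param ci Intercellular CO2 concentrations (umol mol^-1).
#' @param a Net assimilation rates (umol m^-2 s^-1).
#' @param leaf_temp Leaf temperature (degC).
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(sample_id, ci, a, leaf_temp = 25) {
  if (length(ci) != length(a)) stop("ci and a must have equal length")
  if (any(!is.finite(ci)) || any(ci <= 0)) stop("ci must be > 0")
  structure(list(sample_id = as.character(sample_id),
                 observations = data.frame(ci = as.numeric(ci),
                                           a = as.numeric(a)),
                 leaf_temp = leaf_temp),
            class = "aci_curve")
}

#' The measurement protocol's stepped cuvette CO2 sequence
#'
#' The 12-step sequence used when recording A/Ci curves: start at growth
#' CO2, step down to probe the Rubisco-limited region, then up to
#' saturation (umol mol^-1).
#'
#' @return Integer vector of length 12.
#' @export
default_ci_steps <- function() {
  c(400, 200, 50, 100, 300, 400, 600, 900, 1200, 1500, 1800, 2000)
}

#' Fit the FvCB model to an A/Ci curve
#'
#' Minimizes the sum of squared residuals between observed assimilation and
#' [forward_assimilation()] over (Vc,max, J, Rd) -- and TPU when
#' `fit_tpu = TRUE` -- with mesophyll conductance fixed at `gm_fixed`.
#' The optimizer is bounded Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`) restarted from a log-spaced 3 x 3 x 2 grid of
#' (Vc,max, J, Rd) starts; the best SSE wins, ties broken toward lower
#' Vc,max. Each observation is labeled with its limiting process at the
#' optimum, and `j_identifiable` is `FALSE` when no observation is
#' RuBP-limited (the J estimate is then unconstrained by the data, as for
#' leaves that are never electron-transport limited).
#'
#' @param curve An [aci_curve()] with at least 5 observations.
#' @param kinetics A [kinetic_constants()] object.
#' @param gm_fixed Fixed mesophyll conductance (mol m^-2 s^-1 bar^-1);
#'   `Inf` for no mesophyll resistance.
#' @param fit_tpu Include the TPU limitation and fit its rate.
#' @param bounds Named list of length-2 numeric bounds for `vcmax`, `j`,
#'   `rd`, `tpu`.
#' @param max_iter Maximum optimizer iterations per start.
#' @return A list of class `fvcb_fit` with elements `params`
#'   ([fvcb_params()]), `limitation_state`, `sse`, `converged`,
#'   `j_identifiable`, `fitted`, `n_obs`.
#' @export
fit_aci <- function(curve, kinetics = kinetic_constants(), gm_fixed = 0.3,
                    fit_tpu = FALSE,
                    bounds = list(vcmax = c(5, 500), j = c(10, 600),
                                  rd = c(0, 10), tpu = c(3, 60)),
                    max_iter = 200) {
  stopifnot(inherits(curve, "aci_curve"))
  obs <- curve$observations
  if (nrow(obs) < 5L) {
    stop("A/Ci fitting needs at least 5 observations, got ", nrow(obs))
  }
  best <- aci_multistart(obs, kinetics, gm_fixed, fit_tpu, bounds,
                         max_iter, fix_j = FALSE)
  if (is.null(best$par)) {
    stop("A/Ci optimizer failed from every start for sample ",
         curve$sample_id)
  }
  params <- best$make_params(best$par)
  det <- forward_assimilation(params, kinetics, obs$ci, details = TRUE)

  # J is identifiable only if disabling the RuBP branch (profile fit with
  # J effectively unbounded) costs a significantly worse SSE (extra-sum-
  # of-squares F test at the 1% level, one parameter difference); this
  # guards against noise letting J graze a single point on curves that
  # are in truth Rubisco-limited everywhere.
  j_identifiable <- FALSE
  if (any(det$limitation == "RuBP")) {
    no_j <- aci_multistart(obs, kinetics, gm_fixed, fit_tpu, bounds,
                           max_iter, fix_j = TRUE)
    df_resid <- nrow(obs) - length(best$par)
    if (is.null(no_j$par)) {
      j_identifiable <- TRUE
    } else if (no_j$sse - best$sse > 1e-6 && df_resid >= 1L) {
      f_stat <- (no_j$sse - best$sse) / (best$sse / df_resid + 1e-12)
      j_identifiable <- f_stat > stats::qf(0.99, 1, df_resid)
    }
  }

  structure(list(
    sample_id = curve$sample_id,
    params = params,
    limitation_state = det$limitation,
    sse = best$sse,
    converged = best$converged,
    j_identifiable = j_identifiable,
    fitted = det$a,
    n_obs = nrow(obs)
  ), class = "fvcb_fit")
}

# Bounded Levenberg-Marquardt least squares restarted from a log-spaced
# grid; with fix_j = TRUE the RuBP branch is disabled (J pinned far above
# any limiting value) and only the remaining parameters are fit.
aci_multistart <- function(obs, kinetics, gm_fixed, fit_tpu, bounds,
                           max_iter, fix_j = FALSE) {
  par_names <- c("vcmax", if (!fix_j) "j", "rd", if (fit_tpu) "tpu")
  lower <- vapply(bounds[par_names], `[`, numeric(1), 1L)
  upper <- vapply(bounds[par_names], `[`, numeric(1), 2L)
  make_params <- function(p) {
    fvcb_params(vcmax = p[["vcmax"]],
                j = if (fix_j) 1e7 else p[["j"]],
                rd = p[["rd"]],
                tpu = if (fit_tpu) p[["tpu"]] else NULL, gm = gm_fixed)
  }
  resid_fun <- function(p) {
    pred <- tryCatch(
      forward_assimilation(make_params(p), kinetics, obs$ci),
      error = function(e) rep(1e6, nrow(obs))
    )
    obs$a - pred
  }
  starts <- expand.grid(
    vcmax = exp(seq(log(20), log(400), length.out = 3)),
    j = exp(seq(log(30), log(500), length.out = 3)),
    rd = c(0.5, 5)
  )
  if (fix_j) starts <- unique(starts[, c("vcmax", "rd")])
  if (fit_tpu) starts$tpu <- max(obs$a) / 3 + 2

  best <- list(par = NULL, sse = Inf, converged = FALSE,
               make_params = make_params)
  for (i in seq_len(nrow(starts))) {
    p0 <- unlist(starts[i, par_names, drop = FALSE])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    best$converged <- best$converged || fit$info %in% 1:4
    sse <- sum(fit$fvec^2)
    if (is.null(best$par) || sse < best$sse - 1e-9 ||
        (abs(sse - best$sse) <= 1e-9 &&
         fit$par[["vcmax"]] < best$par[["vcmax"]])) {
      best$par <- fit$par
      best$sse <- sse
    }
  }
  best
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat(sprintf(
    "FvCB fit (%s): Vc,max = %.1f, J = %.1f, Rd = %.2f umol m-2 s-1\n",
    x$sample_id, x$params$vcmax, x$params$j, x$params$rd))
  cat(sprintf("  SSE = %.3f over %d points; converged: %s; J identifiable: %s\n",
              x$sse, x$n_obs, x$converged, x$j_identifiable))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit An `fvcb_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fvcb_fit"))
  payload <- list(
    sample_id = fit$sample_id,
    params = list(vcmax = fit$params$vcmax, j = fit$params$j,
                  rd = fit$params$rd, tpu = fit$params$tpu,
                  gm = if (is.infinite(fit$params$gm)) "Inf"
                       else fit$params$gm),
    limitation_state = fit$limitation_state,
    sse = fit$sse,
    converged = fit$converged,
    j_identifiable = fit$j_identifiable
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
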