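kin <- kinetic_constants()

test_that("forward model honors the compensation point and saturation", {
  p <- fvcb_params(120, 180, 1.5, gm = Inf)
  expect_equal(forward_assimilation(p, kin, kin$gamma_star), -1.5)
  p2 <- fvcb_params(120, 1e9, 1.5, gm = Inf)
  expect_equal(forward_assimilation(p2, kin, 1e7), 120 - 1.5,
               tolerance = 1e-4)
})

test_that("finite-gm closed form matches a damped fixed-point oracle", {
  fp_oracle <- function(p, ci, tol = 1e-10) {
    km <- kin$Kc * (1 + kin$O / kin$Ko)
    cc <- ci
    repeat {
      ac <- p$vcmax * (cc - kin$gamma_star) / (cc + km) - p$rd
      aj <- p$j * (cc - kin$gamma_star) / (4 * cc + 8 * kin$gamma_star) -
        p$rd
      cc_new <- ci - min(ac, aj) / p$gm
      if (abs(cc_new - cc) < tol) break
      cc <- cc + 0.5 * (cc_new - cc)
    }
    min(p$vcmax * (cc - kin$gamma_star) / (cc + km),
        p$j * (cc - kin$gamma_star) / (4 * cc + 8 * kin$gamma_star)) - p$rd
  }
  p <- fvcb_params(120, 180, 1.5, gm = 0.3)
  for (ci in c(50, 100, 300, 600, 1200, 2000)) {
    expect_equal(forward_assimilation(p, kin, ci), fp_oracle(p, ci),
                 tolerance = 1e-8)
  }
})

test_that("gm -> infinity limit agrees with the infinite-gm closed form", {
  ci <- seq(50, 2000, by = 50)
  p_inf <- fvcb_params(150, 210, 1.2, gm = Inf)
  a_inf <- forward_assimilation(p_inf, kin, ci)
  # the residual drawdown scales as 1/gm (~ A/gm * dA/dCc)
  p_big <- fvcb_params(150, 210, 1.2, gm = 1e6)
  expect_lt(max(abs(a_inf - forward_assimilation(p_big, kin, ci))), 1e-5)
  p_huge <- fvcb_params(150, 210, 1.2, gm = 1e7)
  expect_lt(max(abs(a_inf - forward_assimilation(p_huge, kin, ci))), 1e-6)
})

test_that("assimilation is non-decreasing in Ci", {
  ci <- seq(20, 2000, by = 10)
  for (pars in list(fvcb_params(60, 90, 0.8, gm = 0.3),
                    fvcb_params(300, 330, 2, gm = Inf),
                    fvcb_params(150, 210, 1.2, tpu = 12, gm = 0.3))) {
    a <- forward_assimilation(pars, kin, ci)
    expect_true(all(diff(a) >= -1e-10))
  }
})

test_that("TPU limitation caps assimilation when enabled", {
  p <- fvcb_params(150, 210, 1.2, tpu = 9, gm = Inf)
  det <- forward_assimilation(p, kin, c(100, 2000), details = TRUE)
  expect_equal(det$a[2], 3 * 9 - 1.2)
  expect_equal(det$limitation[2], "TPU")
})

test_that("noiseless curves are recovered to well under 0.5 percent", {
  truth <- fvcb_params(150, 210, 1.2, gm = Inf)
  cv <- simulate_aci(truth, kin, noise_sd = 0, seed = 1)
  fit <- fit_aci(cv, kin, gm_fixed = Inf)
  expect_lt(abs(fit$params$vcmax - 150) / 150, 0.005)
  expect_lt(abs(fit$params$j - 210) / 210, 0.005)
  expect_true(fit$converged)
  expect_true(fit$j_identifiable)
  expect_equal(length(fit$limitation_state), 12L)
})

test_that("fitted SSE never exceeds the truth's SSE on noiseless data", {
  for (s in 1:5) {
    truth <- fvcb_params(80 + 40 * s, 120 + 50 * s, 1, gm = 0.3)
    cv <- simulate_aci(truth, kin, noise_sd = 0, seed = s)
    fit <- fit_aci(cv, kin, gm_fixed = 0.3)
    sse_truth <- sum((cv$observations$a -
                        forward_assimilation(truth, kin,
                                             cv$observations$ci))^2)
    expect_lte(fit$sse, sse_truth + 1e-8)
  }
})

test_that("Rubisco-limited-everywhere curves flag J as unidentifiable", {
  truth <- fvcb_params(20, 200, 1.2, gm = 0.3)
  cv <- simulate_aci(truth, kin, noise_sd = 0.3, seed = 2)
  fit <- fit_aci(cv, kin, gm_fixed = 0.3)
  expect_false(fit$j_identifiable)
  expect_lt(abs(fit$params$vcmax - 20) / 20, 0.1)
})

test_that("fitting rejects curves with too few observations", {
  cv <- aci_curve("short", c(100, 300, 600, 1200), c(5, 12, 18, 22))
  expect_error(fit_aci(cv, kin), "at least 5")
})

test_that("fit results serialize to JSON with all diagnostic fields", {
  cv <- simulate_aci(fvcb_params(150, 210, 1.2, gm = 0.3), kin,
                     noise_sd = 0.2, seed = 9)
  fit <- fit_aci(cv, kin, gm_fixed = 0.3)
  txt <- fit_to_json(fit)
  parsed <- jsonlite::fromJSON(txt)
  expect_equal(parsed$params$vcmax, fit$params$vcmax)
  expect_equal(parsed$sse, fit$sse)
  expect_equal(length(parsed$limitation_state), 12L)
  expect_type(parsed$j_identifiable, "logical")
})
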