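# Synthetic-data generator: trait populations for a six-genotype tobacco
# trial, trait-linked leaf reflectance spectra, and FvCB-driven A/Ci curves
# with known ground truth. Every downstream stage of the package is
# testable against these generators without any external data.

#' Describe one genotype's trait population
#'
#' @param name Genotype label.
#' @param n_samples Number of leaves sampled.
#' @param vcmax_mean,vcmax_sd Mean and SD of Vc,max (umol m^-2 s^-1).
#' @param vcmax_range Length-2 closed interval to which draws are clipped
#'   (truncated-normal sampling by rejection).
#' @param j_ratio_mean,j_ratio_sd Per-sample ratio J1800 / Vc,max.
#' @param j_observed When `FALSE`, J1800 is recorded as missing (leaves
#'   that are never electron-transport limited, so J cannot be derived
#'   from their A/Ci curves).
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, n_samples, vcmax_mean, vcmax_sd,
                          vcmax_range, j_ratio_mean = 1.4,
                          j_ratio_sd = 0.15, j_observed = TRUE) {
  if (!is_count(n_samples)) stop("n_samples must be a positive count")
  if (!is_number(vcmax_sd) || vcmax_sd < 0) stop("vcmax_sd must be >= 0")
  if (length(vcmax_range) != 2L || vcmax_range[1] >= vcmax_range[2]) {
    stop("vcmax_range must be an interval with lower < upper")
  }
  if (!is_number(j_ratio_mean) || j_ratio_mean <= 0) {
    stop("j_ratio_mean must be > 0")
  }
  structure(list(name = as.character(name), n_samples = as.integer(n_samples),
                 vcmax_mean = vcmax_mean, vcmax_sd = vcmax_sd,
                 vcmax_range = as.numeric(vcmax_range),
                 j_ratio_mean = j_ratio_mean, j_ratio_sd = j_ratio_sd,
                 j_observed = isTRUE(j_observed)),
            class = "genotype_spec")
}

#' Default genotype roster of the emulated tobacco trial
#'
#' Six genotypes: three wild types, an overexpression line (SFX) and two
#' Rubisco antisense knockdowns. Sample sizes, Vc,max means, SDs and
#' ranges follow the emulated trial's summary statistics; per-genotype
#' J1800/Vc,max ratio means are the quotients of the corresponding J1800
#' and Vc,max means. The double knockdown (SSuD) has `j_observed = FALSE`:
#' its leaves are never electron-transport limited, so J1800 is missing.
#'
#' @return List of [genotype_spec()] objects (n = 38, 39, 39, 18, 45, 33;
#'   212 samples of which 179 carry J1800).
#' @export
tobacco_genotypes <- function() {
  list(
    genotype_spec("PetitHavana", 38, 166.0, 38.2, c(80.3, 238.1),
                  j_ratio_mean = 1.39),
    genotype_spec("Samsun", 39, 239.5, 61.8, c(139.9, 344.6),
                  j_ratio_mean = 1.12),
    genotype_spec("Mammoth", 39, 208.1, 65.1, c(89.0, 339.9),
                  j_ratio_mean = 1.12),
    genotype_spec("SFX", 18, 244.7, 15.6, c(218.1, 271.1),
                  j_ratio_mean = 1.16),
    genotype_spec("SSuS", 45, 160.6, 55.3, c(29.9, 241.5),
                  j_ratio_mean = 1.42),
    genotype_spec("SSuD", 33, 55.3, 37.9, c(14.5, 166.2),
                  j_observed = FALSE)
  )
}

# truncated-normal draw by rejection; cap attempts per draw
rtruncnorm_reject <- function(n, mean, sd, lower, upper,
                              max_attempts = 10000L) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate draw: mean outside the truncation range")
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(max_attempts)) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
      x <- NA_real_
    }
    if (is.na(x)) {
      stop("truncated-normal rejection sampler exceeded ", max_attempts,
           " attempts; range is too far from the mean")
    }
    out[i] <- x
  }
  out
}

#' Simulate a trait population
#'
#' Draws Vc,max per genotype from a truncated normal (mean, SD, clipped to
#' the genotype's range) and J1800 as a per-sample ratio times Vc,max;
#' genotypes with `j_observed = FALSE` get `NA` J1800.
#'
#' @param genotypes List of [genotype_spec()] objects.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Tibble with columns `sample_id`, `genotype`, `vcmax`, `j1800`.
#' @export
simulate_traits <- function(genotypes = tobacco_genotypes(), seed = 1) {
  if (length(genotypes) == 0L) stop("genotype list must be non-empty")
  ok <- vapply(genotypes, inherits, logical(1), "genotype_spec")
  if (!all(ok)) stop("all elements must be genotype_spec objects")
  with_seed(substream_seed(seed, "traits"), {
    rows <- lapply(genotypes, function(g) {
      vcmax <- rtruncnorm_reject(g$n_samples, g$vcmax_mean, g$vcmax_sd,
                                 g$vcmax_range[1], g$vcmax_range[2])
      ratio <- rtruncnorm_reject(g$n_samples, g$j_ratio_mean, g$j_ratio_sd,
                                 0.2, Inf)
      j1800 <- if (g$j_observed) ratio * vcmax else rep(NA_real_,
                                                        g$n_samples)
      tibble::tibble(
        sample_id = sprintf("%s_%02d", g$name, seq_len(g$n_samples)),
        genotype = g$name, vcmax = vcmax, j1800 = j1800
      )
    })
    do.call(rbind, rows)
  })
}

#' Configuration of the reflectance generator
#'
#' The generative model for one leaf's spectrum is
#' `R(i, w) = B(w) * (1 + h(w) * s_i) * (1 + e_i) + n_iw`, where `B` is a
#' smooth leaf baseline profile, `h(w) = sum_k c_k g_k(w)` sums Gaussian
#' bumps `g_k` centered on pigment/water features with trait-coupling
#' coefficients `c_k`, `s_i` is the standardized trait of sample `i` plus
#' Gaussian link noise (`trait_link_sd`), `e_i` is a per-sample
#' multiplicative brightness error, and `n_iw` is additive band noise.
#' Bands inside `signal_free_ranges` receive noise only (`h = 0`), and all
#' values are clipped to (0, 1).
#'
#' @param wavelength_grid Wavelengths in nm, strictly increasing.
#' @param baseline_profile Per-band baseline reflectance in (0, 1);
#'   defaults to the packaged leaf profile interpolated onto the grid.
#' @param signal_components Data frame with columns `center`, `width`
#'   (nm) and `coef` (dimensionless trait coupling).
#' @param trait_link_sd SD of the Gaussian link noise between the
#'   standardized trait and its spectral expression; this bounds how well
#'   any regression can recover the trait from the spectra.
#' @param noise_sd_additive SD of i.i.d. additive reflectance noise.
#' @param noise_sd_multiplicative SD of the per-sample brightness error.
#' @param signal_free_ranges List of length-2 nm intervals carrying no
#'   trait signal.
#' @return An object of class `spectra_config`.
#' @export
spectra_config <- function(wavelength_grid = 350:2500,
                           baseline_profile = NULL,
                           signal_components = default_signal_components(),
                           trait_link_sd = 0.45,
                           noise_sd_additive = 0.003,
                           noise_sd_multiplicative = 0.015,
                           signal_free_ranges = list(c(2200, 2500))) {
  if (is.unsorted(wavelength_grid, strictly = TRUE)) {
    stop("wavelength_grid must be strictly increasing")
  }
  if (is.null(baseline_profile)) {
    baseline_profile <- baseline_reflectance(wavelength_grid)
  }
  if (length(baseline_profile) != length(wavelength_grid)) {
    stop("baseline_profile must match the wavelength grid")
  }
  if (any(baseline_profile <= 0) || any(baseline_profile >= 1)) {
    stop("baseline_profile must lie strictly inside (0, 1)")
  }
  if (any(signal_components$width <= 0)) stop("component widths must be > 0")
  structure(list(wavelength_grid = wavelength_grid,
                 baseline_profile = baseline_profile,
                 signal_components = signal_components,
                 trait_link_sd = trait_link_sd,
                 noise_sd_additive = noise_sd_additive,
                 noise_sd_multiplicative = noise_sd_multiplicative,
                 signal_free_ranges = signal_free_ranges),
            class = "spectra_config")
}

#' Default trait-coupled spectral components
#'
#' Gaussian bumps at the green peak, red edge, NIR plateau and the
#' 1450/1940 nm water features; higher-capacity leaves are darker in the
#' visible (more pigment) and differ mildly in the water/structure bands.
#'
#' @return Data frame with columns `center`, `width`, `coef`.
#' @export
default_signal_components <- function() {
  data.frame(
    center = c(550, 705, 870, 1450, 1700, 1940),
    width = c(40, 25, 100, 60, 80, 60),
    coef = c(-0.10, -0.12, 0.02, 0.05, 0.04, 0.06)
  )
}

#' Smooth leaf baseline reflectance profile
#'
#' Spline interpolation of the packaged anchor profile (low visible with a
#' green bump, NIR plateau near 0.46, water-absorption dips near 1450 and
#' 1940 nm) onto an arbitrary wavelength grid.
#'
#' @param wavelengths Target wavelengths (nm).
#' @return Reflectance values in (0, 1).
#' @export
baseline_reflectance <- function(wavelengths = 350:2500) {
  path <- system.file("extdata", "leaf_baseline_profile.csv",
                      package = "photostack", mustWork = TRUE)
  anchors <- utils::read.csv(path)
  out <- stats::spline(anchors$wavelength, anchors$reflectance,
                       xout = wavelengths, method = "natural")$y
  pmin(pmax(out, 0.01), 0.95)
}

#' Simulate trait-linked reflectance spectra
#'
#' @param traits Tibble from [simulate_traits()] (needs `sample_id` and
#'   `vcmax`).
#' @param config A [spectra_config()].
#' @param seed Integer seed.
#' @return Numeric matrix (samples x bands) with sample ids as rownames
#'   and wavelengths (nm) as column names; values in (0, 1).
#' @export
simulate_spectra <- function(traits, config = spectra_config(), seed = 1) {
  stopifnot(inherits(config, "spectra_config"))
  if (nrow(traits) < 1L) stop("need at least one trait record")
  if (anyDuplicated(traits$sample_id)) stop("duplicate sample ids")
  wl <- config$wavelength_grid
  n <- nrow(traits)
  p <- length(wl)

  # summed trait-coupling pattern h(w), zeroed in signal-free ranges
  h <- rep(0, p)
  for (k in seq_len(nrow(config$signal_components))) {
    cmp <- config$signal_components[k, ]
    h <- h + cmp$coef * exp(-((wl - cmp$center)^2) / (2 * cmp$width^2))
  }
  for (rg in config$signal_free_ranges) {
    h[wl >= rg[1] & wl <= rg[2]] <- 0
  }

  z <- as.numeric(scale(traits$vcmax))
  if (any(!is.finite(z))) z <- rep(0, n)  # constant trait: no signal

  with_seed(substream_seed(seed, "spectra"), {
    s <- z + stats::rnorm(n, 0, config$trait_link_sd)
    bright <- 1 + stats::rnorm(n, 0, config$noise_sd_multiplicative)
    signal <- 1 + outer(s, h)                       # n x p
    X <- signal * bright *
      matrix(config$baseline_profile, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p, 0, config$noise_sd_additive), n, p)
    X <- pmin(pmax(X, 1e-4), 1 - 1e-4)
    dimnames(X) <- list(traits$sample_id, as.character(wl))
    X
  })
}

#' Simulate one A/Ci curve
#'
#' Forward FvCB assimilation at each cuvette step plus i.i.d. Gaussian
#' measurement noise.
#'
#' @param params An [fvcb_params()] object (the ground truth).
#' @param kinetics A [kinetic_constants()] object.
#' @param ci_steps Ci levels (umol mol^-1); default is the 12-step
#'   measurement sequence of [default_ci_steps()].
#' @param noise_sd SD of additive noise on A (umol m^-2 s^-1).
#' @param seed Integer seed.
#' @param sample_id Leaf identifier attached to the curve.
#' @param leaf_temp Leaf temperature (degC), metadata only.
#' @return An [aci_curve()] object.
#' @export
simulate_aci <- function(params, kinetics = kinetic_constants(),
                         ci_steps = default_ci_steps(), noise_sd = 0.5,
                         seed = 1, sample_id = "leaf", leaf_temp = 25) {
  if (length(ci_steps) < 1L || any(ci_steps <= 0)) {
    stop("ci_steps must be non-empty and strictly positive")
  }
  if (!is_number(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  a_true <- forward_assimilation(params, kinetics, ci_steps)
  a <- with_seed(substream_seed(seed, "aci"),
                 a_true + stats::rnorm(length(ci_steps), 0, noise_sd))
  aci_curve(sample_id, ci_steps, a, leaf_temp)
}

#' Simulate A/Ci curves for a whole trait table
#'
#' One curve per trait record. Records with missing J1800 (leaves that are
#' never electron-transport limited) are simulated with an effectively
#' non-limiting electron transport rate (3.2 x Vc,max + 30), so downstream
#' fits flag `j_identifiable = FALSE` for them.
#'
#' @param traits Tibble from [simulate_traits()].
#' @inheritParams simulate_aci
#' @param gm Mesophyll conductance used for the ground-truth curves.
#' @param rd Day respiration used for the ground-truth curves.
#' @return Named list of [aci_curve()] objects.
#' @export
simulate_aci_dataset <- function(traits, kinetics = kinetic_constants(),
                                 ci_steps = default_ci_steps(),
                                 noise_sd = 0.5, seed = 1, gm = 0.3,
                                 rd = 1.2) {
  curves <- vector("list", nrow(traits))
  for (i in seq_len(nrow(traits))) {
    j <- traits$j1800[i]
    if (is.na(j)) j <- 3.2 * traits$vcmax[i] + 30
    pars <- fvcb_params(vcmax = traits$vcmax[i], j = j, rd = rd, gm = gm)
    curves[[i]] <- simulate_aci(pars, kinetics, ci_steps, noise_sd,
                                seed = seed + i,
                                sample_id = traits$sample_id[i])
  }
  names(curves) <- traits$sample_id
  curves
}
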