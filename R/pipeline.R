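# End-to-end analysis pipeline: simulate -> fit A/Ci -> benchmark ->
# band-block importance, with all artifacts and a run manifest written to
# an output directory. Configuration is a plain named list (or YAML file)
# with one master seed flowing into named substreams per stage.

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; mandatory for every stage.
#' @param stages Which stages to run (subset of `"simulate"`,
#'   `"fit_aci"`, `"benchmark"`, `"importance"`).
#' @param repeats,folds,test_fraction Benchmark protocol.
#' @param importance_repetitions Resplits for the ablation study.
#' @param reduced_grids Use compact learner search spaces.
#' @param inner_folds Inner tuning folds for the learners.
#' @param wavelength_step Grid spacing (nm) of the simulated spectra
#'   (1 reproduces the full 2151-band grid; larger values thin the grid
#'   for fast runs).
#' @param aci_noise_sd Gas-exchange noise SD (umol m^-2 s^-1).
#' @param genotypes Genotype roster for the simulation stage.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed, stages = c("simulate", "fit_aci",
                                                 "benchmark", "importance"),
                       repeats = 10L, folds = 10L, test_fraction = 0.1,
                       importance_repetitions = 20L, reduced_grids = TRUE,
                       inner_folds = 5L, wavelength_step = 1L,
                       aci_noise_sd = 0.5,
                       genotypes = tobacco_genotypes()) {
  if (missing(seed) || !is_count(abs(seed) + 1)) {
    stop("an integer seed is mandatory")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, repeats = as.integer(repeats),
                 folds = as.integer(folds), test_fraction = test_fraction,
                 importance_repetitions = as.integer(importance_repetitions),
                 reduced_grids = reduced_grids,
                 inner_folds = as.integer(inner_folds),
                 wavelength_step = as.integer(wavelength_step),
                 aci_noise_sd = aci_noise_sd, genotypes = genotypes),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields override the [run_config()] defaults; the genotype
#' roster stays the packaged default unless a `genotypes` list (name,
#' n_samples, vcmax_mean, vcmax_sd, vcmax_range, ...) is given.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must set a seed")
  if (is.null(raw$out_dir)) stop("config must set out_dir")
  gen <- if (!is.null(raw$genotypes)) {
    lapply(raw$genotypes, function(g) do.call(genotype_spec, g))
  } else {
    tobacco_genotypes()
  }
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(run_config)), "genotypes"))]
  args$genotypes <- gen
  do.call(run_config, args)
}

#' Run the end-to-end analysis
#'
#' Executes the configured stages in order, writing: traits, spectra and
#' A/Ci CSVs (simulate); fitted FvCB parameters per leaf (fit_aci); the
#' tidy benchmark results and summary plus the deployable stack model
#' JSON (benchmark); the ablation importance table (importance); and a
#' run manifest (config hash, seed, versions, per-stage timings).
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, a list with the in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  out <- list()
  timings <- list()
  manifest_hash <- digest::digest(unclass(config))

  # validate protocol feasibility before any fitting
  n_total <- sum(vapply(config$genotypes, function(g) g$n_samples,
                        integer(1)))
  n_train <- n_total - round(n_total * config$test_fraction)
  if (n_train < 2L * config$folds) {
    stop("precondition: folds = ", config$folds,
         " needs at least ", 2L * config$folds,
         " training samples, have ", n_train)
  }

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    message(sprintf("[photostack] stage %-10s done in %6.1fs", name,
                    timings[[name]]))
    res
  }

  if ("simulate" %in% config$stages) {
    out$traits <- stage("simulate", {
      traits <- simulate_traits(config$genotypes, seed = seed)
      grid <- seq(350L, 2500L, by = config$wavelength_step)
      spectra <- simulate_spectra(traits,
                                  spectra_config(wavelength_grid = grid),
                                  seed = seed)
      curves <- simulate_aci_dataset(traits, noise_sd = config$aci_noise_sd,
                                     seed = seed)
      write_traits_csv(traits, file.path(config$out_dir, "traits.csv"))
      write_spectra_csv(spectra, file.path(config$out_dir, "spectra.csv"))
      write_aci_csv(curves, file.path(config$out_dir, "aci.csv"))
      out$spectra <- spectra
      out$curves <- curves
      traits
    })
  }

  if ("fit_aci" %in% config$stages) {
    out$aci_fits <- stage("fit_aci", {
      curves <- out$curves %||%
        load_aci_csv(file.path(config$out_dir, "aci.csv"))
      fits <- lapply(curves, fit_aci)
      tab <- do.call(rbind, lapply(fits, function(f) {
        tibble::tibble(sample_id = f$sample_id, vcmax_fit = f$params$vcmax,
                       j_fit = f$params$j, rd_fit = f$params$rd,
                       sse = f$sse, converged = f$converged,
                       j_identifiable = f$j_identifiable)
      }))
      data.table::fwrite(tab, file.path(config$out_dir, "aci_fits.csv"))
      tab
    })
  }

  if (any(c("benchmark", "importance") %in% config$stages)) {
    spectra <- out$spectra %||%
      load_spectra_csv(file.path(config$out_dir, "spectra.csv"))
    traits <- out$traits %||%
      load_traits_csv(file.path(config$out_dir, "traits.csv"))
    y <- stats::setNames(traits$vcmax, traits$sample_id)
    specs <- default_learner_specs(inner_folds = config$inner_folds,
                                   seed = seed,
                                   reduced = config$reduced_grids)
  }

  if ("benchmark" %in% config$stages) {
    out$benchmark <- stage("benchmark", {
      bench <- run_benchmark(spectra, y, specs, repeats = config$repeats,
                             folds = config$folds,
                             test_fraction = config$test_fraction,
                             seed = seed, trait = "vcmax")
      data.table::fwrite(bench$results,
                         file.path(config$out_dir, "eval_results.csv"))
      data.table::fwrite(bench$summary,
                         file.path(config$out_dir, "eval_summary.csv"))
      stack <- fit_stack(spectra, y, specs, folds = config$folds,
                         seed = seed)
      save_stack_model(stack,
                       file.path(config$out_dir, "stack_vcmax.json"))
      bench
    })
  }

  if ("importance" %in% config$stages) {
    out$importance <- stage("importance", {
      imp <- block_importance(spectra, y, ablation_learner_specs(seed),
                              repetitions = config$importance_repetitions,
                              test_fraction = config$test_fraction,
                              seed = seed)
      data.table::fwrite(imp$table,
                         file.path(config$out_dir, "importance.csv"))
      imp
    })
  }

  manifest <- list(config_hash = manifest_hash, seed = seed,
                   stages = config$stages,
                   package_version = as.character(
                     utils::packageVersion("photostack")),
                   r_version = R.version.string,
                   timings_seconds = timings)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(config$out_dir, "manifest.json"))
  out$manifest <- manifest
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
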