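#!/usr/bin/env Rscript
# Stage 3: the headline benchmark. Ten repeated 9:1 train/test splits of
# the 212 x 2151 dataset; within each training set, 10-fold out-of-fold
# predictions from the six learners feed the level-2 LASSO; three-phase
# metrics (train with CV, train without CV, test) for each learner and
# the stack, for Vc,max and for J1800 (179 leaves). Writes tidy results
# under results/run/ plus results/benchmark_summary.csv and the
# deployable stack model JSON.
#
# Expected findings: individual test R2 in the 0.6-0.8 range with the
# stack at or above the best individual learner, and level-2 weights
# spread across several learners (negative weights are legitimate).

library(photostack)

cfg <- run_config(out_dir = "results/run", seed = 42,
                  stages = "benchmark", repeats = 10, folds = 10,
                  inner_folds = 3)
out <- run_pipeline(cfg)
print(out$benchmark)

# J1800 benchmark over the 179 leaves with observed values
traits <- load_traits_csv("results/run/traits.csv")
spectra <- load_spectra_csv("results/run/spectra.csv")
keep <- !is.na(traits$j1800)
yj <- setNames(traits$j1800[keep], traits$sample_id[keep])
specs <- default_learner_specs(inner_folds = 3, seed = 42, reduced = TRUE)
bench_j <- run_benchmark(spectra[names(yj), ], yj, specs, repeats = 10,
                         folds = 10, seed = 43, trait = "j1800")
print(bench_j)

both <- rbind(out$benchmark$summary, bench_j$summary)
write.csv(both, "results/benchmark_summary.csv", row.names = FALSE)

st <- load_stack_model("results/run/stack_vcmax.json")
cat("\nLevel-2 weights (Vc,max stack):\n")
print(level2_coefficients(st))
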