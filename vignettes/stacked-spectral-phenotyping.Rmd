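---
title: "Stacked spectral phenotyping of photosynthetic capacities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked spectral phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Leaf photosynthetic capacity is usually summarized by two biochemical
parameters: the maximum Rubisco carboxylation rate $V_{c,max}$ and the
electron transport rate supporting RuBP regeneration at the measurement
light level, here called $J_{1800}$ (1800 µmol m⁻² s⁻¹ PAR). Both are
derived from A/Ci gas-exchange curves, which take tens of minutes per
leaf. Hyperspectral leaf reflectance (350–2500 nm, 2151 one-nanometre
bands) takes seconds, so a regression from spectra to capacities turns a
gas-exchange bottleneck into a high-throughput assay. This package
implements that pipeline end to end: FvCB curve fitting to produce the
reference capacities, six spectral regression learners, and a stacked
(level-2) combination of them, plus a synthetic-data generator that
emulates a six-genotype tobacco field trial so the whole pipeline is
testable with known ground truth.

## The FvCB model and A/Ci fitting

Net assimilation is the minimum of a Rubisco-limited, an
RuBP-regeneration-limited and (optionally) a TPU-limited rate:

$$A = \min(A_c, A_j, A_p), \quad
A_c = \frac{V_{c,max}(C_c - \Gamma^*)}{C_c + K_c(1 + O/K_o)} - R_d, \quad
A_j = \frac{J(C_c - \Gamma^*)}{4 C_c + 8\Gamma^*} - R_d,$$

with $A_p = 3\,TPU - R_d$. Chloroplastic CO₂ is $C_c = C_i - A/g_m$;
for finite mesophyll conductance $g_m$ each branch becomes a quadratic
in $A$ whose lower root is taken (computed in the cancellation-free
form; `forward_assimilation()` matches a damped fixed-point oracle to
1e-8 in the tests).

Defaults, all exposed in `kinetic_constants()` and `fit_aci()`:
$\Gamma^* = 42.75$, $K_c = 404.9$ µmol mol⁻¹, $K_o = 278.4$,
$O = 210$ mmol mol⁻¹ (the common tobacco values at 25 °C) and
$g_m = 0.3$ mol m⁻² s⁻¹ bar⁻¹. These are package defaults, not
measured values; parameters are reported at measurement temperature and
no temperature normalization is applied. The TPU branch is off by
default.

`fit_aci()` minimizes the residual sum of squares over
$(V_{c,max}, J, R_d)$ with $g_m$ fixed, using bounded
Levenberg–Marquardt restarted from a log-spaced 3×3×2 grid
(bounds $V_{c,max} \in [5, 500]$, $J \in [10, 600]$, $R_d \in [0, 10]$,
$TPU \in [3, 60]$); ties in SSE resolve toward the lower $V_{c,max}$.
Each observation is labeled with its limiting process at the optimum.

**J identifiability.** Leaves with strongly reduced Rubisco (the
emulated double knockdown) are never electron-transport limited, so $J$
cannot be derived from their curves. A naive "is any point
RuBP-limited?" label is fragile: with measurement noise the optimizer
can let $J$ graze a single point even when the true curve never
touches the RuBP branch, and an extra free parameter absorbs roughly
$1/n$ of the SSE by chance alone. We therefore use a profile test:
refit with the RuBP branch disabled and require the restricted SSE to
be significantly worse (extra-sum-of-squares F test, 1% level) before
declaring $J$ identifiable.

## The synthetic trial

`tobacco_genotypes()` encodes the emulated trial: six genotypes with
n = 38, 39, 39, 18, 45, 33 (212 leaves, 179 with observed $J_{1800}$),
per-genotype $V_{c,max}$ means, SDs and ranges spanning 14.5–344.6
µmol m⁻² s⁻¹ (23.8-fold), and per-sample ratios
$J_{1800}/V_{c,max}$ (means 1.12–1.42, SD 0.15) so the two capacities
are correlated but not collinear. Draws are truncated normals by
rejection (capped at 10 000 attempts).

Spectra follow a deliberately simple generative model
(`spectra_config()`):

$$R(i, \lambda) = B(\lambda)\,\bigl(1 + h(\lambda)\, s_i\bigr)\,
(1 + \varepsilon_i) + \eta_{i\lambda},$$

where $B$ is a smooth leaf baseline (low visible reflectance with a
green bump, NIR plateau ≈ 0.46, water dips at 1450/1940 nm; packaged as
a spline-interpolated anchor table), $h(\lambda)$ sums Gaussian bumps at
pigment and water features with small coupling coefficients,
$\varepsilon_i$ is a per-sample brightness error (SD 0.015, emulating
leaf-clip repositioning), and $\eta$ is additive band noise (SD 0.003).
Bands in 2200–2500 nm carry no trait signal by default, mirroring the
finding that those blocks are uninformative. $s_i$ is the standardized
trait plus Gaussian *link noise* (`trait_link_sd`, default 0.45): the
spectrally visible pigment/structure axis tracks the gas-exchange
capacity imperfectly, which caps the attainable test $R^2$ near
$1/(1+0.45^2) \approx 0.83$ and puts realized test $R^2$ in the 0.6–0.8
range typical of field studies, instead of the near-1.0 a noiseless
linear link would give. What passing tests therefore show is that the
pipeline ranks and combines learners correctly under a realistic
signal-to-noise regime — not that the simple rank-one signal captures
real leaf optics (no radiative-transfer realism, no instrument noise
model, one averaged spectrum per leaf).

A/Ci curves are generated by the forward FvCB model at the 12-step
cuvette sequence 400, 200, 50, 100, 300, 400, 600, 900, 1200, 1500,
1800, 2000 µmol mol⁻¹ plus i.i.d. Gaussian noise (default SD
0.5 µmol m⁻² s⁻¹). Leaves whose $J_{1800}$ is unobserved are simulated
with a non-limiting electron transport rate ($3.2 V_{c,max} + 30$) so
downstream fits genuinely cannot identify $J$ for them.

## Preprocessing

Each band is z-scored, $z = (R_i - \bar R_i)/S_{R_i}$, with the mean
and *sample* SD (n−1; the defining equation does not fix the
denominator) estimated on training data only — the standardizer is
refit inside every resampling loop, so no test or held-fold statistic
ever enters a model. Zero-variance bands are recorded and dropped.
Replicate scans are averaged arithmetically.

For ablation studies the spectrum is tiled into 22 blocks A–V: A is
350–400 nm, then contiguous 100-nm blocks to 2500 nm. Blocks are
half-open $[l, h)$ so each 1-nm band belongs to exactly one block
(the printed "350–400, 400–500" notation is ambiguous at boundaries);
the final block's upper edge is closed so 2500 nm is covered. Block A
thus holds 50 bands, V holds 101, and the grid totals 2151.

## The six learners

All six consume the identical standardized matrix. Selection rules are
fixed per learner; the grids are package defaults exposed in
`default_grid()` (the compact `reduced = TRUE` grids are used by the
repeated benchmark protocols):

* **LASSO** — `glmnet` path (100 penalties), penalty by inner-CV RMSE,
  ties toward the larger penalty. Fitted without re-standardization
  (the bands are already z-scored).
* **PLS** — SIMPLS, implemented in-package (no PLS regression package
  is declared as a dependency); the number of latent variables (1–30,
  reduced 1–10) by inner-CV RMSE. For a univariate response SIMPLS
  coincides with PLS1, which the tests verify against an independent
  implementation, and at full rank it reproduces OLS.
* **ANN** — single-hidden-layer back-propagation network (`nnet`,
  linear output) trained on a frozen supervised linear input
  compression: the leading PLS latent scores of the standardized bands
  (rank 15 reduced / 30 full), refit inside every tuning fold so inner
  CV stays leakage-free. A first layer that is linear in thousands of
  collinear bands gains nothing from seeing them individually, while
  the quasi-Newton optimizer behind `nnet` scales quadratically in the
  weight count — compression makes the learner faster and more stable,
  and anchoring the directions on the response keeps them insensitive
  to uninformative bands. Hidden size and weight decay are chosen by
  inner-CV RMSE, the response is standardized internally, and the
  final model averages several random-initialization nets (3 reduced /
  5 full), since single nonconvex fits are noisy.
* **SVM** — ε-regression with RBF kernel (`e1071`); cost by inner-CV
  RMSE, kernel width from the median pairwise-distance heuristic
  (± a factor grid in the full search space).
* **RF** — `ranger`; variables-per-split tuned by out-of-bag error.
* **GP** — exact Gaussian-process regression with RBF + noise kernel,
  implemented in-package; hyperparameters (length-scale, signal and
  noise variance) by Type-II maximum likelihood (L-BFGS-B on the log
  marginal likelihood with random restarts). Tests check predictions
  against the closed-form posterior mean.

Inner tuning uses k-fold CV (default 5, 3 in the heavy benchmark runs)
rather than literal leave-one-out: fold-wise CV is the same selection
rule at a fraction of the cost. All fits are deterministic given the
spec seed.

## Stacking

Within a training set, samples are split into 10 folds; for each fold,
the standardizer and all six learners are fit on the other 9 folds and
predict the held fold, giving an out-of-fold (OOS) prediction matrix in
which no entry was produced by a model that saw that sample — any inner
fit sees N−2 of the original folds once the test tenth is also counted
out. The level-2 model is a LASSO on the raw OOS matrix (intercept
included, *no* standardization of the predictions, 100-penalty path,
penalty by 10-fold CV, ties toward the sparser model). Negative weights
are admissible — an anti-correlated learner is useful with a negative
coefficient, and the benchmark reproduces that behavior. For
deployment, the six learners are refit on the full training set and
combined with the level-2 weights.

Evaluation follows a three-phase protocol over repeated independent
9:1 train/test splits (default 10 repeats): `train_cv` (OOS
predictions vs training truth — the honest training-phase metric),
`train_full` (full-training refits applied back to the training data,
optimistic by construction) and `test` (deployed models on the held-out
tenth). $R^2$ is the coefficient of determination $1 - SSE/SST$, which
can be negative; RMSE is in µmol m⁻² s⁻¹.

Block importance repeats, per repetition, a fresh 9:1 split, a
full-spectrum baseline fit per learner, and one refit per excluded
block, recording $100\,(R^2_{excl} - R^2_{base})/R^2_{base}$; the
per-repetition pairing keeps the comparison matched. What varies across
repetitions is the split (the repetition scheme is not otherwise
pinned down by the protocol), and the same learner specs are reused for
every ablation.

## Numerical and design choices

* **Ties**: SSE ties in A/Ci multi-starts go to the lower $V_{c,max}$;
  inner-CV ties to the earlier (simpler) candidate; level-2 penalty
  ties to the larger penalty.
* **Degenerate inputs**: constant responses, NaN predictors, fewer than
  5 A/Ci points, single-sample standardizers and empty exclusions are
  rejected with messages, never silently accepted.
* **Randomness**: one master seed flows through named substreams
  (traits, spectra, noise, splits, folds, learners, level-2), so stages
  are independently reproducible; library code restores the caller's
  RNG state.
* **Serialization**: stack models write a JSON envelope with clear-text
  level-2 weights plus an authoritative serialized payload, so reloaded
  models reproduce predictions bit-identically; CSV writers emit 17
  significant digits so data round-trip exactly.

## Problem sizes used by tests and the acceptance script

The package's own verification runs at sizes chosen to exercise the
full protocol while staying desk-scale: the stacking benchmark at the
full 212 × 2151 with 10 repeats, 10 stacking folds, 3 inner tuning
folds and the compact grids; FvCB recovery on 200 noisy curves (plus
noiseless checks); the band-block null on the full 212-leaf roster at a
2-nm grid with compact stability-oriented specs, ablating the three
signal-free blocks against the full-spectrum baseline over 20
resplits. For that ablation the ANN's compression rank is fixed at
two, matching the generator's latent dimensionality (one trait axis,
one brightness axis) — deeper latent directions are noise-driven and
rotate when uninformative bands are removed, which would measure
compression instability rather than the information content of the
ablated blocks. Unit tests use a 10–25-nm grid where band resolution is
irrelevant.

## Known limitations

* The spectra generator is rank-one in the trait signal; it cannot
  probe how learners exploit multiple independent spectral axes.
* $J_{1800}$ enters the synthetic spectra only through its correlation
  with $V_{c,max}$, so J-prediction benchmarks measure propagation of
  that correlation, not an independent J signal.
* Kinetic constants and $g_m$ are fixed defaults; fitted capacities are
  conditional on them, as with any A/Ci fitting utility.
* With six strongly correlated level-1 predictions, individual level-2
  weights are not stable across splits (only the combined prediction
  is); interpret coefficient tables as distributions over repeats.
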