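---
title: "Forecasting stratified incidence rates with a dual-pathway attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting stratified incidence rates with a dual-pathway attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asircast)
```

## Scope and data model

`asircast` forecasts one-year-ahead age-standardized incidence rates (ASIR,
cases per 100,000) for a panel of 24 sex–age strata: two sexes crossed with
twelve five-year bands from 40–44 to 95+, observed annually. The canonical
panel spans 1990–2021, giving 24 series of 32 observations — small data by
deep-learning standards, which drives many of the design choices below
(tiny batches, aggressive regularization, a linear escape hatch in the
architecture).

The real extract this layout mirrors is access-restricted, so the package
ships a generator (`synthetic_spec()`, `generate_panel()`) rather than
data. Everything downstream is tested against that generator's known ground
truth.

## Preprocessing

1. **Standardization.** Each series is Z-scored with the population SD
   formula, so the fit window has mean exactly 0 and SD exactly 1. The fit
   window is the *training years only* by default: fitting on all 32 years
   would let post-boundary levels shift the training inputs, a quiet form
   of leakage. Because the upstream description of this step does not say
   which window was used, the fit-on-everything reading is kept available
   (`scaler_fit = "all"` in `run_config()`), but the leakage-free mode is
   the default and the one the test suite guards (mutating any post-2016
   value must change no scaler statistic, no training feature and no
   training metric).
2. **Feature engineering.** Six columns per series, 144 in total: the
   standardized value, its 3-year trailing moving average ("trend"), the
   residual from that average, the 3-year trailing population SD
   ("volatility"), the male−female gap of the series' age band (identical
   column assigned to both sex slots), and an EWMA with decay 0.3. The
   dimension accounting (24 original + 5 × 24 derived = 144) admits exactly
   one column per family per series, so the trend block uses the 3-year
   average only; the 5- and 7-year averages are still computed and exposed
   as diagnostics (`$diagnostics`) but never enter the model input. All
   rolling operators are right-aligned with an expanding warm-up for the
   first years — this preserves the series length (so a 32-year panel
   yields the full 22 windows) and uses no future information, which the
   suite asserts by mutation.
3. **Windowing and split.** Ten-year sliding windows with a one-year
   horizon and step; a 32-year panel gives 22 supervised samples with
   target years 2000–2021. The sequential split at boundary year 2016
   yields 17 training and 5 test samples; all test targets postdate all
   training targets (walk-forward).

Derived features are computed *after* standardization, matching the stated
ordering of the preprocessing steps; the sex-difference block is therefore
on the standardized scale.

## Architecture

The forward pass, in order:

- **Input projection** (per time step): affine map to the hidden width,
  batch normalization over the flattened batch × time axis, ReLU. Batch
  normalization uses running statistics in evaluation mode; batches here
  are as small as 13 samples, which batch statistics tolerate because the
  normalized axis pools batch and time (≥ 130 rows).
- **Stacked BiLSTM**: the six classic gate equations per direction, states
  concatenated per step; inter-layer dropout (inverted scaling) only in
  training mode. The forget-gate bias is initialized at 1 so cells start by
  remembering — standard practice; the source is silent on initialization.
  All other weights use a seeded uniform fan-in scheme.
- **Multi-scale attention**: the stated scale ranges — short 1–3, medium
  3–6, long 6–10 years — are read as *lags counted back from the most
  recent window step* (lag 1 = last step); that is the only reading under
  which "short-term" means "recent". Boundary lags 3 and 6 belong to both
  adjacent scales, as the ranges overlap. Each scale runs four heads
  (`tanh` scoring, scaled softmax over the scale's steps only, weighted
  sum); the four head contexts are concatenated and linearly projected back
  to the sequence width before the three scale contexts are concatenated.
  This keeps the cross-scale bookkeeping at exactly three context vectors
  while honoring four heads per scale. The attention projection width `d_a`
  and the scaling factor `d_k` both default to the hidden width; neither is
  stated upstream.
- **Output**: one shared ReLU layer, then 24 independent affine heads — one
  per stratum — evaluated in parallel.
- **Residual fusion**: `Ŷ = α Ŷ_deep + (1−α) X_avg W_res` with `X_avg` the
  time-average of the input window. `α` is parameterized as the sigmoid of
  an unconstrained scalar initialized at logit 0 (α = 0.5): the convex form
  requires α ∈ [0,1] and no constraint mechanism is stated. `α` is a
  scalar, not a per-group vector — the fusion equation shows a single α.
  Both pathway outputs are retrievable pre-fusion
  (`component_contribution()`).
- **Ensemble**: optional simple average over members differing only by
  initialization seed (base + m), the simplest reproducible reading of
  "slight parameter perturbations".

There is no torch backend in this environment: the network *and its
backpropagation* are hand-written in base R. The gradients are the part
most likely to silently rot, so the test suite pins them twice — against
central-difference numerical gradients on a two-layer configuration with
batch normalization active, and against a straight-line scalar
implementation of the complete forward pass.

## Training

Adam (β₁ 0.9, β₂ 0.999) minimizes MSE over all 24 groups jointly on
standardized targets — the loss is never named upstream; MSE matches the
RMSE fitness the swarm uses. Learning rate follows cosine annealing from
the configured rate to 1/100 of it over `max_epochs`, no restarts.
Gradients are clipped to global norm 1. Early stopping watches a
*time-ordered* validation tail (the last four training target years,
2013–2016 on the canonical panel) — a random validation subset would leak
future structure — and the best-validation parameters are restored.
Metrics (MAE, MSE, RMSE, MAPE as a fraction, R²) are reported pooled over
groups and samples, by default after mapping back to the rate scale; MAPE
on standardized, zero-centered values would be ill-defined, but a
`standardized` mode is kept because the upstream scale is ambiguous.
Elements with a true value of zero are excluded from MAPE and counted.

## Hyperparameter search

Standard real-valued PSO over a mixed space: particles move on continuous
internal coordinates; integer/ordinal dimensions are decoded by
nearest-value rounding (ties half up) at evaluation time, so the velocity
and position equations remain exact. `r1`, `r2` are drawn per dimension
(the common convention; a per-particle mode exists). Velocity is clamped to
20% of each dimension's range — unstated upstream, but a small box without
clamping bounces particles off the walls. Default bounds (hidden width
{16, 32, 64, 128}, layers {1, 2, 3}, dropout [0.05, 0.5], learning rate
log-scaled in [1e-4, 1e-2], heads {2, 4, 8}) were chosen to contain the
reported optimum (64, 2, 0.15, 0.002, 4); the bounds actually searched
upstream are not stated. Fitness is validation RMSE at a fixed
per-point-derived seed, so a search is reproducible and a repeated
evaluation of the same point returns the same value. The iteration cap is
20; an optional stagnation window (off by default) implements the
otherwise-undefined "convergence conditions".

## Interpretability

Attribution is computed at the (time step × feature column) level and
aggregated to the 24 sex–age groups through the column manifest — summed
`|φ|` for importance views, summed signed φ for local decompositions. The
reference is the training-set mean neighborhood: backgrounds are training
inputs, optionally augmented with Gaussian-jittered copies (SD 5% of each
column's SD). The printed one-point gradient form violates completeness on
nonlinear models, so the default integrates gradients at stratified
midpoints along the reference-to-input path (expected-gradients style) and
reports the per-sample completeness gap; the literal one-point mode remains
behind `mode = "one_point"`. Multi-output attribution targets the sum of
the 24 outputs by default (which output the upstream figures explain is
unstated), with a per-group option. Exact Shapley values by subset
enumeration (`exact_shap_small()`, ≤ 12 features) serve as the oracle: the
axioms (efficiency, symmetry, dummy) and a permutation-average
reformulation are asserted in the tests, the gradient approximation is
exact on linear models and correlation-checked on nonlinear ones.

## What the synthetic world does and does not establish

The generator produces: a female baseline per band rising with age plus a
configurable male offset; linear, logistic or piecewise (one change-point,
independent slopes) trends; independent Gaussian noise per series-year,
heteroscedastic across bands (SD proportional to the band's baseline
level), clipped at zero. Defaults — 12 bands, 1990–2021, piecewise trend
with the change-point at the mid-year, base noise SD 2 per 100,000, male
offset 25 per 100,000 — are one fixed choice of "realistic" and are not
tuned per test. It does *not* emulate GBD uncertainty-interval propagation,
COVID-era shocks as a mechanism, or cross-band correlated noise. A green
behavioural test therefore establishes that the machinery orders methods
correctly on panels with this structure — not that the full-scale error
magnitudes from the restricted extract are reproduced; those magnitudes are
explicitly out of reach at desk scale.

The behavioural analogue tests run a reduced network (hidden width 16, one
layer, two heads per scale, learning rate 0.01, ≤ 300 epochs) so ten-seed
replications finish in minutes on one CPU. The learning rate is higher than
the full-scale default because the reduced model trains on 13 samples and
the default rate under-converges within the epoch budget; this is an
optimization-schedule choice for the scaled-down world, fixed once.

## Numerical choices and degenerate inputs

- Population (divide-by-n) SD everywhere a Z-score or rolling SD is taken.
- Constant series are rejected at scaler fitting (zero SD).
- Softmax logits are max-shifted before exponentiation.
- Ordinal decoding ties round half up (documented tie-break).
- Failed swarm evaluations (errors, non-finite fitness) count as +Inf and
  the search continues.
- A non-finite training loss aborts with a diagnostic rather than
  continuing silently.
- The engineered feature matrix is rank-deficient by construction
  (residual + trend ≡ original; the sex-difference column is duplicated
  across sex slots); anything that solves least squares against it must be
  rank-aware (the tests use an SVD pseudoinverse).

## Known limitations

- One invariant from the design contract cannot hold in its strongest
  form: the *full model's* output is not invariant to perturbing input
  years outside every attention scale's mask, because the recurrent encoder
  propagates any input change into the hidden states the attention reads.
  The masking contract is real but lives at the attention layer's input —
  perturbing unmasked steps of the hidden sequence leaves the attention
  summary unchanged — and that is where the suite asserts it.
- Confidence bands for forecasts are not implemented; no construction is
  stated upstream.
- The core contract is the one-year horizon. Longer direct horizons are
  supported in the windowing (`make_windows(horizon = k)`), but recursive
  multi-step forecasting — feeding predictions back through the feature
  engineering — is not implemented.
- Kernel SHAP for the full 1440-input model is out of scope; attribution
  beyond 12 features relies on the gradient approximation.
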