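---
title: "Methods: dynamically gated mixture-of-experts yield estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamically gated mixture-of-experts yield estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

`wheatmoe` estimates county-level winter-wheat yield (kg/ha) from ten monthly
feature trajectories spanning the growing season, September through June of
the harvest year: four optical signals (NDVI, EVI, NIRv, red reflectance),
two biophysical variables (LAI, Fpar), two meteorological drivers (relative
humidity from the Magnus formula, cumulative radiation in MJ/m²), and two
static county covariates (DEM elevation, soil organic carbon). Each sample is
a 10 x 10 matrix (months x features) with a scalar label; static covariates
are broadcast across the ten rows so a single input width of 10 serves the
whole sequence.

## Model

A linear embedding maps the 10 features to a hidden width $d$ and adds
sinusoidal positional encoding. Two parallel branches read the embedded
season: a Transformer encoder (4 post-norm layers, 8 heads, no causal mask —
estimation sees the full season) and a 2-layer bidirectional LSTM with
per-direction width $d/2$. Their per-step outputs are concatenated into
$h \in \mathbb{R}^{t \times 2d}$.

A two-layer gating network acts on the temporal mean $h_{avg}$:
$g = \mathrm{softmax}(W_2\,\mathrm{GELU}(W_1 h_{avg} + b_1) + b_2)$,
producing assignment probabilities over five structurally heterogeneous
experts (two-layer GELU; wide ReLU; narrow SiLU at width $d/2$; single-layer
GELU; three-layer ReLU). Only the Top-2 experts by probability are evaluated
(sparse activation); per-expert linear adapters standardize native output
widths to $d$, and the mixture is the gate-weighted sum
$o_i = \sum_{j=1}^{2} w_{ij}\, o_{ij}$ using the **raw** softmax entries —
Top-2 weights are deliberately not renormalized (a config switch enables
renormalization, off by default). A fusion head concatenates the mixture
with the Transformer final state (last time-step row) and the LSTM final
state (last forward plus last backward hidden), then maps
$3d \to 512 \to 256 \to 1$ with GELU nonlinearities.

### Resolved design ambiguities

Several architectural details are under-determined by the recipe the package
follows; we fixed them once and document them here:

* **Hidden width $d$** is nowhere stated. Default `model_config("paper")`
  uses $d = 128$, which makes the stated gate hidden width ($256 = 2d$)
  and fusion widths natural. Because published FLOP totals depend on $d$,
  FLOP accounting is validated by *ordering* (dense > sparse > no-mixture),
  never by absolute totals.
* **Expert input** is the temporal mean $h_{avg}$, matching the gating
  convention, not the full $t \times 2d$ sequence; the printed expert shapes
  are not mutually composable, so widths were resolved as: E0 $2d\to d\to d$
  (GELU, dropout 0.2/0.1), E1 $2d\to 2d\to d$ (ReLU, 0.3), E2
  $2d\to d/2\to d/2$ (SiLU, 0.1), E3 $2d\to d$ (GELU), E4
  $2d\to d/2\to d/2\to d$ (ReLU, 0.2 each).
* **Adapters are per-expert** — a shared adapter is impossible when native
  output widths differ ($d$ vs $d/2$).
* **Top-k ties** break to the lowest expert index, deterministically across
  platforms.
* **Dropout schedule** "hierarchical 0.1–0.3": embedding 0.1, encoder 0.1,
  LSTM inter-layer 0.2, experts as defined above, fusion 0.1.

The network and its backpropagation are written in base R (no deep-learning
framework is assumed); the $O(b\,h\,t^2)$ attention arithmetic is a small
compiled core. Every hand-derived gradient — attention, LSTM BPTT, layer
normalization, the sparse gate routing — is verified against central finite
differences in the test suite for every model variant.

## Training and evaluation protocol

Training uses Adam, Huber loss on min-max-scaled targets, a batch size of 32,
and global gradient-norm clipping at 1.0. The scaler is fitted **on the
training split only** and records every sample key it saw, so leakage is
auditable rather than assumed. Model selection keeps the parameters with the
best validation loss; validation is monitoring-only unless an early-stop
patience is set (the recipe is silent on this, so both behaviours are
available). Huber $\delta = 1$ on targets scaled into $[0,1]$ keeps almost
all residuals in the quadratic branch. The `"paper"` training profile is the
published recipe (lr $10^{-4}$, 600 epochs); the `"desk"` profile ($d = 32$,
lr $10^{-3}$, 100 epochs) was chosen a priori for single-CPU test budgets —
a narrower model and a proportionally larger constant learning rate for a
shorter schedule — and is used by the heavier acceptance tests.

Two evaluation strategies are provided: fixed held-out test years with the
remaining samples split 8:2 into train/validation at the sample level (the
granularity of the 8:2 rule is our choice; the source states only the
ratio), and a leave-one-year-out rolling protocol with a mean row. The
progressive in-season protocol retrains on sequences truncated to each
cutoff month, quantifying how early yield becomes predictable. Metrics
(R², RMSE, MAE) are always computed after inverse target scaling, in kg/ha.
The per-sample agreement statistic is
$100\cdot\min(y,\hat y)/\max(y,\hat y)$, reported to one decimal with
half-away-from-zero rounding. Error stratification bins samples by terciles
of actual yield (the "low/medium/high" ranges are shown without stated
edges; terciles are our convention) and summarizes raw errors as
`estimated - actual`, so systematic underestimation appears as negative
medians.

## Attribution

Feature attributions use expected gradients, a Shapley-value approximation:
path integrals of the input gradient from background samples to the sample
being explained, averaged over a fixed background (default cap 100 training
samples, 8 background draws x 8 midpoint path points per sample). The
estimator and background size are our choices — the source names the method
family but not the estimator. Per-cell attributions on the 10 x 10 input are
summed over months per feature before taking means of absolute values for
the ranking. For a linear model the estimator reduces to the closed form
$\beta_j (x_j - \bar b_j)$, which the tests verify exactly; local accuracy
(attributions summing to prediction minus mean background prediction) holds
up to path-discretization error.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, not
any particular region: a bell-shaped latent NDVI trajectory (base 0.18,
amplitude 0.45 with ~15% county and ~8% county-year variation, peak in
April, width 2 months); EVI, NIRv, red reflectance, LAI and Fpar as monotone
transforms of the latent NDVI plus independent noise, which induces the
strong index-family collinearity that correlation screening must flag;
seasonal relative humidity and radiation with persistent county offsets;
lognormal county elevations and truncated-normal soil carbon drawn once per
county. Yield is linear in standardized season summaries with signed
effects — negative for RHum (the dominant driver, −600 kg/ha per typical
unit), DEM (−300) and SoC (−150), positive for Fpar (+300), NIRv (+250) and
Rad (+150) — plus Gaussian noise (sd 150 kg/ha) around a 5500 kg/ha base,
truncated at a 100 kg/ha floor. The `"late"` timing variant computes the
summaries over months 8–10 only and adds a county-year late-season humidity
anomaly, so most of the signal is invisible before spring; this is the world
used to validate the progressive protocol.

A green test on this world establishes that the pipeline recovers a known
nonlinear-in-features, linear-in-summaries signal under realistic
collinearity and noise. It does **not** establish real-data skill: the
generator has no spatial structure, no phenological regime shifts, no
extreme-weather years, and its yield function is far simpler than reality.

## Numerical choices and limitations

Min-max scaling maps constant training columns to 0 by convention;
validation/test values may leave $[0,1]$. Gap filling interpolates interior
missing months linearly, extends season ends with the nearest observation,
and drops county-years with fewer than 6 observed months per dynamic
feature. Exact (not tanh-approximate) GELU is used throughout. Evaluation
mode is bitwise deterministic; training is deterministic given the seed on a
single CPU. "Sliding-window time-series feature extraction" is interpreted as
one window per county-year covering the full season; sub-season windows with
stride would multiply samples per county-year and are deliberately not
implemented. Known limitations: no learning-rate schedules, no hyperparameter
search, no GPU path, and FLOP totals are convention-dependent (2mn per dense
map, matrix products only).
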