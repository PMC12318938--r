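# wheatmoe

County-level wheat yield estimation from monthly growing-season trajectories,
using a dynamically gated sparse mixture-of-experts sequence model — for
agricultural remote-sensing researchers who want the full estimation pipeline
(feature engineering, training protocols, in-season forecasting,
interpretability, ablations) runnable and testable on a single CPU without
any external data or deep-learning framework.

## The model

One sample is a season tensor: 10 months (September → June of the harvest
year) × 10 features — NDVI, EVI, NIRv, red reflectance, LAI, Fpar, relative
humidity (Magnus formula), radiation, DEM, SoC — with a yield label in
kg/ha. A linear embedding plus sinusoidal positional encoding feeds two
parallel branches: a 4-layer/8-head Transformer encoder and a 2-layer
bidirectional LSTM. Their concatenation `h ∈ R^{t×2d}` is pooled over time
and routed by a softmax gating network

    g = softmax(W2 · GELU(W1 · h_avg + b1) + b2)

to five architecturally heterogeneous expert networks, of which only the
Top-2 by probability are evaluated (sparse activation). Per-expert linear
adapters standardize output widths to `d` and the mixture is the raw
gate-weighted sum `o = Σ_j w_j · o_j` (weights not renormalized). A fusion
head maps `[o; final_T; final_L]` through 512 → 256 → 1. Training follows
the recipe: Adam (lr 1e-4), Huber loss on min-max-scaled targets fitted on
the training split only, batch 32, gradient clipping at 1.0, 600 epochs
("paper" profile; a CPU-scale "desk" profile uses d = 32, lr 1e-3, 100
epochs). Evaluation: R², RMSE, MAE in kg/ha; fixed held-out test years with
an 8:2 train/validation split; leave-one-year-out rolling tests; progressive
monthly truncation for in-season forecasting; expected-gradients Shapley
attribution; ablation variants with analytic FLOP accounting. The network
and its backpropagation are implemented in base R (with a small compiled
attention core); all gradients are verified against finite differences in
the test suite.

## Worked example

```r
library(wheatmoe)

ds    <- make_fixture(0)                         # 8 counties x 5 years, synthetic
split <- fixed_year_split(ds$samples, 2021, seed = 1)
model <- build_variant("stf_moe", model_config("desk"), seed = 1)
fit   <- train(model, ds$samples, split, train_config("desk", epochs = 50, seed = 1))

yhat <- predict_yield(fit$model, apply_scaler(fit$scaler, ds$samples[split$test]), fit$scaler)
metric_set(vapply(ds$samples[split$test], `[[`, numeric(1), "y"), yhat)
#> R2 = 0.8718, RMSE = 301.06 kg/ha, MAE = 226.32 kg/ha (n = 8)

sample_accuracy(6361.0, 5764.208)                # min/max agreement statistic
#> [1] 90.6
```

The held-out year 2021 was never seen by the scaler or the optimizer (the
`fit$access_log` records every sample key each stage touched); R² = 0.87
means the desk-scale model explains 87% of the held-out yield variance on
the fixture world, with a typical error around 300 kg/ha against yields near
5500 kg/ha. The same pipeline scales to the default synthetic world
(100 counties × 10 years), where the acceptance suite requires held-out
R² ≥ 0.8 and that the dominant injected driver (relative humidity, negative
effect) ranks first by mean absolute attribution.

A file-based CLI covers the whole pipeline
(`simulate | features | train | evaluate | rolling | early | explain | ablate`):

```sh
Rscript -e 'wheatmoe::run_cli()' simulate --seed 0 --out runs/sim
Rscript -e 'wheatmoe::run_cli()' train --data runs/sim/data.csv --out runs/fit --epochs 50
```

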