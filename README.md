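# rerpgrid

Mass univariate regression modeling of event-locked, multi-channel time
series — regression ERPs (rERPs) for EEG-style data, in R.

## What it does

Event-related potential (ERP) research has traditionally summarized
event-locked recordings by averaging epochs within conditions. Averaging is a
special case of regression: the average ERP is exactly the intercept of an
intercept-only linear model fit at each time point and channel. rerpgrid
takes the general view. At every cell of the time × channel grid it fits the
same linear model

```
y(epoch) = beta_0(t, c) + beta_1(t, c) * x_1(epoch) + ... + e,   e ~ N(0, sigma^2)
```

across epochs, turning each model coefficient into an estimated *waveform*
beta_j(t, c). This supports categorical designs (where it reproduces and
generalizes condition averages), continuous covariates, interactions, and
nonlinear predictor effects via polynomial and B-spline expansions — while
every classical regression diagnostic (standard errors, t and p values, R²,
AIC/BIC, hat values, Cook's distances, residuals) becomes a time series on
the same grid.

The combinatorial load is real — 3 s of 32-channel data sampled at 250 Hz
yields 750 × 32 = 24,000 per-cell datasets, and comparing three candidate
models means 72,000 fits — so the fitting engine recognizes the common case
of epoch-constant predictors and reuses a single QR decomposition across all
cells, with results bit-identical to standalone per-cell fits.

Main components:

- **`epochs_table` / `validate_epochs` / `load_epochs`** — a validated
  long-format container (one row per epoch × time sample) with explicit
  column roles and lossless CSV/TSV round trips.
- **`parse_formula` / `build_design_matrix`** — a self-contained Wilkinson-
  style formula compiler: `~ 1 + a * x + pow(x, 2) + bspline(x, df = 5)`,
  treatment-coded categoricals, interaction expansion, explicit intercept
  control, and a choice of erroring on rank-deficient designs (naming the
  aliased columns) or fitting by pseudoinverse.
- **`fit_grid`** — the mass univariate engine; returns a grid container
  whose per-cell statistics are retrieved as tidy tibbles with
  `get_attribute`, subset with `slice_grid`, and exported with `export_tidy`.
- **`compare_models` / `likelihood_ratio`** — per-cell AIC comparison across
  candidate models (with a selection partition of the grid) and
  likelihood-ratio tests with a numerical check that the models are nested.
- **`build_wide_design` / `verify_continuous`** — an equivalent single wide
  regression (one block of coefficients per latency) used to verify the
  segmented per-cell fits against an independent formulation of the same
  estimator.
- **`simulation_spec` / `simulate_epochs`** — a ground-truth generator:
  Gaussian-bump coefficient waveforms, balanced categorical or normal
  continuous predictors, i.i.d. Gaussian noise, single-seed determinism.
- **`cmd_simulate` / `cmd_fit` / `cmd_compare` / `cmd_verify_continuous`** —
  config-driven pipeline entry points (also runnable via
  `inst/cli/rerpgrid.R`) whose outputs are byte-identical across runs,
  machines' directories, and worker counts.

## Worked example

Simulate a 100-epoch, 4-channel study with a two-level stimulus factor whose
effect is a 3 µV Gaussian bump peaking at 300 ms, then fit the generating
model at every cell:

```r
library(rerpgrid)

ep <- simulate_epochs(simulation_spec(seed = 42))
ep
#> <epochs_table> 100 epochs x 151 times x 4 channels
#> predictors: a

g <- fit_grid(ep, "~ 1 + a")
g
#> <fit_grid> 151 times x 4 channels | model: ~ 1 + a
#>   n = 100 epochs, p = 2 ((Intercept), a[trtmt])
#>   time range [-0.1, 0.5], channels: ch1, ch2, ch3, ch4

beta <- get_attribute(g, "beta")
beta[abs(beta$time - 0.3) < 1e-9 & beta$channel == "ch3", ]
#> # A tibble: 2 × 4
#>    time channel coefficient   value
#>   <dbl> <chr>   <chr>         <dbl>
#> 1   0.3 ch3     (Intercept) -0.0248
#> 2   0.3 ch3     a[trtmt]     3.06
```

The estimated stimulus effect at the true peak (ch3, 300 ms) is 3.06 against
a ground truth of 3. Model comparison partitions the grid by per-cell AIC:

```r
comp <- compare_models(list(average  = fit_grid(ep, "~ 1"),
                            stimulus = g))
table(comp$model[comp$selected])
#>  average stimulus
#>      231      373
```

The stimulus model wins where the effect bump lives; the plain average
suffices elsewhere. Finally, the segmented per-cell fits agree with the
single wide continuous regression to machine precision:

```r
verify_continuous(ep, "~ 1 + a")$max_abs_diff
#> [1] 2.220446e-15
```

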