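---
title: "Methods: mass univariate regression ERP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass univariate regression ERP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerpgrid)
```

## The model

An event-locked dataset is a rectangular panel: $N$ epochs, each recorded at
the same $T$ time samples on $C$ channels, with per-epoch (or, in general,
per-sample) predictor values. At every cell $(t, c)$ of the time × channel
grid, rerpgrid fits the linear model

$$
y_i(t, c) \;=\; \mathbf{x}_i^\top \boldsymbol\beta(t, c) + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2(t, c)) \text{ i.i.d.},
$$

across epochs $i = 1, \dots, N$, by ordinary least squares. Each coefficient
$\beta_j(t, c)$, traced over $t$, is a *regression ERP* (rERP) waveform. The
classical average ERP is the special case $\mathbf{x}_i = 1$: the intercept
of the intercept-only model at each cell is exactly the per-cell mean, and
the package treats this identity as a primary invariant (it holds to
$< 10^{-12}$, limited only by floating-point summation order).

The Gaussian noise is assumed independent across epochs *within each cell*;
no claim is made about independence across time or channels, and the
per-cell inferential statistics are conditional on the cell. Temporal
autocorrelation of the noise is deliberately not modeled (see Limitations).

### Per-cell statistics

Every fit exposes: `beta`, `se`, `tvalues`, `pvalues`, `residuals`, `rss`,
`sigma2` ($= \mathrm{RSS}/(n - p)$), `loglik`, `aic`, `bic`, `r2`, `r2_adj`,
`hat_diag`, and `cooks_d`. Conventions follow the reference implementations
in `stats` (the test suite pins all of them to `lm`/`summary.lm`/`AIC`/`BIC`/
`hatvalues`/`cooks.distance` at $10^{-10}$ and to an independent
pseudoinverse oracle at $10^{-8}$):

- Gaussian profile log-likelihood:
  $\ell = -\tfrac{n}{2}\left(\log 2\pi + \log(\mathrm{RSS}/n) + 1\right)$.
- $\mathrm{AIC} = 2K - 2\ell$ and $\mathrm{BIC} = K\log n - 2\ell$ with
  $K = p + 1$: the error variance counts as an estimated parameter. This
  matters for model comparison only through differences, where the $+1$
  cancels between models fit to the same cell.
- $R^2$ is centered when the design contains an intercept and uncentered
  otherwise, matching `summary.lm`.
- Cook's distance from the hat diagonal,
  $D_i = \dfrac{e_i^2}{p\,\hat\sigma^2}\cdot\dfrac{h_i}{(1 - h_i)^2}$,
  verified against brute-force leave-one-out refits.

### Numerical core

Fitting uses the pivoted LAPACK QR decomposition. Rank is decided by
singular values against the threshold
$\varepsilon \cdot \max(n, p) \cdot \sigma_{\max}$ (the standard
`Matrix::rankMatrix`-style tolerance). Rank-deficient designs either raise
an error that names the aliased columns (`rank_policy = "error"`, the
default — silent dropping hides specification mistakes) or are solved by
SVD pseudoinverse (`rank_policy = "pinv"`), in which case the effective $p$
is the rank.

### Scale, and the shared-design fast path

Three seconds of 32-channel data at 250 Hz gives $750 \times 32 = 24{,}000$
cells; three candidate models mean $72{,}000$ fits:

```{r accounting}
times <- seq(0, by = 1/250, length.out = 750)
df <- data.frame(epoch_id = 1L, time = times)
for (ch in paste0("ch", 1:32)) df[[ch]] <- 0
grid_dimensions(epochs_table(df, channels = paste0("ch", 1:32)), n_models = 3)
```

When predictors are constant within epoch — the dominant case for
event-locked designs — the design matrix is identical at every cell, so one
QR factorization is computed and reused for all $T \times C$ response
vectors. Because it is literally the same factorization of the same matrix,
the fast path is bit-identical to standalone per-cell fits (asserted with
`expect_identical` in the tests, not merely to tolerance). Predictors that
vary within an epoch fall back to a per-time-point design. Parallelism is by
channel (`parallel::mclapply`) with deterministic gathering; results are
independent of the worker count.

## The formula compiler

Model specification uses a self-contained Wilkinson-style compiler —
`parse_formula` and `build_design_matrix` — rather than `stats::formula`,
because the coding rules here are deliberately fixed and explicit:

- `~ 1 + a + x`, with `1` implied when omitted; `~ 0 + ...` / `~ -1 + ...`
  suppress the intercept.
- Categorical predictors are treatment-coded with labeled columns
  (`a[target]`). The reference level is the lexicographic minimum by
  default, configurable through `coding_scheme(reference = ...)`. With an
  intercept a $k$-level factor contributes $k - 1$ columns; without one, a
  main-effect factor contributes all $k$ indicator columns.
- `a:b` forms products of coded columns; `a*b` expands to `a + b + a:b`;
  duplicate terms are dropped.
- A closed whitelist of transforms: `pow(x, k)`, `bspline(x, df, degree)`,
  `center(x)`, `scale(x)`, `log(x)`. Arbitrary R expressions are rejected —
  a formula is a specification, not code.
- Random-effect syntax `(1 | subject)` is recognized and rejected with an
  explicit message: mixed models are out of scope.

### B-spline bases

`bspline(x, df, degree)` expands a covariate in a clamped B-spline basis
evaluated by the Cox–de Boor recursion (implemented directly; pinned in the
tests against `splines::splineDesign` and a literal recursive oracle).
Boundary knots sit at the data range with full multiplicity; the
`df - degree` interior knots are placed at quantiles of `x`. The full basis
of `df + 1` functions satisfies the partition of unity
$\sum_j B_j(x) \equiv 1$ (to $10^{-12}$, checked over random degrees 0–4 and
knot counts); in a design with an intercept the first basis function is
dropped, which is exact because of that identity.

## Mass model comparison

`compare_models` evaluates candidate models per cell by AIC (or AICc) and
partitions the grid by the minimum; ties resolve to fewer parameters, then
to list order. `likelihood_ratio` computes the $\chi^2$ test for a nested
pair, first *numerically verifying* nesting: the column space of the reduced
design must lie in that of the full design (checked by projecting the
reduced columns with `qr.resid`), so label mistakes cannot silently produce
invalid tests.

## The wide continuous-data formulation

The per-cell ("segmented") formulation has an algebraically equivalent
single-regression form: stack all samples of a channel into one response
vector and build a block design with one copy of the epoch-level predictors
per latency,

$$
\mathbf{X}_{\text{wide}} =
\begin{pmatrix}
\ddots & & \\
& \mathbf{x}_i^\top \text{ at latency } t & \\
& & \ddots
\end{pmatrix},
$$

so one OLS fit of $L \cdot P$ coefficients reproduces the $L$ segmented
fits. `verify_continuous` fits both formulations — different matrix, one QR
of size $NL \times LP$ versus $L$ QRs of size $N \times P$ — and reports the
maximum absolute coefficient discrepancy, which must be below $10^{-8}$ and
is in practice at machine precision. The wide design is built dense: at
verification sizes this is fast, and the point of the construction is an
independent route to the same estimator, not a production code path.

## The synthetic data generator

Ground truth comes from `simulation_spec` / `simulate_epochs`: each design
coefficient is assigned a true waveform built from Gaussian bumps
$A \exp\!\big(-(t - \mu)^2 / 2w^2\big)$ with per-channel weights, and

$$
y_i(t, c) = \sum_j \beta_j(t, c)\, x_{ij} + \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, \sigma^2) \text{ i.i.d.}
$$

Categorical predictors are drawn balanced; continuous predictors are
standard normal. A single integer seed governs every draw, so a spec is a
complete, serializable description of a dataset (the JSON sidecar written by
`cmd_simulate` reproduces the epochs file byte for byte). The noise is white
by construction — temporal autocorrelation is not simulated, consistent with
the per-cell model making no claims across time.

### Default study conditions

The generator defaults are the package's reference study and were fixed
before any tuning: 100 epochs; a −100 to 500 ms window at 250 Hz (151
samples); 4 channels; one balanced two-level stimulus factor under
`~ 1 + a`; an intercept bump (peak 100 ms, SD 40 ms, 2 µV) and an effect
bump (peak 300 ms, SD 80 ms, 3 µV) with graded channel weights; unit
Gaussian noise; seed 1. A 3 µV effect against unit noise at $N = 100$ gives
a per-cell effect SE of $2/\sqrt{N} = 0.2$, i.e. a peak $z \approx 15$:
comfortably detectable, while off-peak cells remain genuinely null.

The recovery and selection studies in the test suite use a deliberately
smaller grid — 61 time points × 2 channels, $N = 200$ — because the
criterion is a bound on the *maximum* error over all cells. For a balanced
two-level contrast the slope estimator has SE $2\sigma/\sqrt{N}$; a
$4\,\mathrm{SE}$ bound on a single cell fails with probability
$\approx 6 \times 10^{-5}$, so across $61 \times 2 = 122$ cells a whole-grid
exceedance occurs in under 1% of replicate studies, and 19-of-20-seeds
success is a sound criterion. These sizes were chosen from this calculation,
not adjusted after observing results.

## Verification strategy

Every numerical claim is checked by at least two independent routes:

- all per-cell statistics against `stats::lm` and friends *and* against a
  from-scratch SVD pseudoinverse oracle;
- Cook's distance against leave-one-out refits;
- the design coder against `stats::model.matrix` on the shared dialect;
- splines against `splines::splineDesign` and a recursive Cox–de Boor
  oracle;
- the wide design against a naive triple-loop construction, and its fit
  against the segmented fits;
- the generator against noiseless exact recovery and the $\sqrt{N}$ error
  law;
- the full pipeline against byte-identity of all output files across
  repeated runs, output directories, and worker counts.

`scripts/acceptance.R --seed <int> --out <path>` reruns the end-to-end
quantities against the installed package and writes them as JSON.

## Limitations

- Independent Gaussian noise per cell: no temporal or spatial error
  correlation, so p-values are per-cell and uncorrected; mass univariate
  inference across the grid (e.g. cluster or FDR control beyond the
  `p_adjust` options of `likelihood_ratio`) is the user's responsibility.
- Fixed effects only; `(1 | subject)` syntax is rejected by design.
- Treatment coding only (no sum/Helmert contrasts).
- The wide formulation is a verification device; it materializes a dense
  $NL \times LP$ matrix and should not be used at full-study sizes.
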