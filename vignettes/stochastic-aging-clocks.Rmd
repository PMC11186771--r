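---
title: "Stochastic variation accumulation as an age signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic variation accumulation as an age signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochclock)
```

## The question the package addresses

Epigenetic and transcriptomic aging clocks predict age remarkably well,
which has been read as evidence for a programmed aging process. stochclock
implements the opposite null model end to end: data whose *only*
age-dependent structure is accumulated random variation on a bounded scale,
plus the standard elastic-net clock construction. If clocks trained on such
data predict a held-out "simulated age" accurately, then clock accuracy by
itself cannot distinguish programmed from stochastic aging. The package
provides the simulators, the clock machinery, and the evaluation harness to
study when and why this works.

## The bulk model

A *ground state* $g \in [0,1]^p$ defines every feature's value at age zero
(uniform random by default, $p = 2000$). A sample of simulated age $a$ is

$$x = \mathrm{bound}\left(g + \varepsilon_0 + \sum_{t=1}^{a} \varepsilon_t\right),
\qquad \varepsilon_t \sim N(0, \sigma^2)^p,$$

where $\varepsilon_0 \sim N(0, 0.01^2)^p$ is a one-time per-sample jitter
emulating inter-individual variation, and `bound` depends on the mode:

* **clamped** — after the jitter and after *every* per-step addition,
  values above 1 are set to 1 and below 0 to 0. We clamp per step rather
  than once at the end: the additions are sequential independent
  applications, and the boundary interaction at each step is the signal
  source (a single terminal clamp is a censored-Gaussian model with
  different dynamics). A switch to the terminal variant is a three-line
  change in `generate_bulk_set()`.
* **logit** — jitter and noise accumulate in logit space and the result
  returns through the inverse logit; values are clipped to
  $[10^{-6}, 1-10^{-6}]$ before the transform because biological beta
  matrices contain exact 0s and 1s.
* **unbounded** — no limit; the negative control. Without a range limit
  positive and negative noise cancel on average and no clock can be
  trained (validation $|r| \le 0.2$).

The age signal in the bounded modes is *regression to the mean*: a feature
starting at 0.1 is clamped from below more often than from above, so its
expectation drifts upward at a rate that decays as memory of the ground
state fades. Elastic-net coefficients mirror this geometry — features
starting low receive positive weights, features starting high negative
ones.

Two consequences are worth knowing. First, hard clamping puts point masses
*at* 0 and 1 (about 12% of features each at $\sigma = 0.2$ after 100
steps); the long-run distribution is uniform between the bounds plus these
boundary atoms, not literally uniform. Second, the per-step $\sigma$ has an
interior optimum: too small and the boundary is never felt, too large and
features mix to their stationary law long before age 100, erasing the
signal. Our sweep (the package's analogue of the published
robustness-to-$\sigma$ panel) puts the plateau at roughly
$\sigma \in [0.015, 0.05]$ with median validation $r \approx 0.98$; we fix
the headline value at $\sigma = 0.03$ and use $\sigma = 0.25$ for the
logit mode, whose plateau sits higher because noise on the logit scale
must be large relative to a logit-space range of several units. At
$\sigma = 0.005$ — smaller than the baseline jitter — the clock still
reaches a median validation $R^2 \approx 0.79$.

## The single-cell methylation model

Each feature (CpG site) is a population of `n_cells` binary cells. Per
time step, a methylated cell stays methylated with maintenance efficiency
$E_m$ and an unmethylated cell becomes methylated with de novo efficiency
$E_d$ ($E_u = 1 - E_d$). The bulk beta value is the methylated fraction.
The stationary level of a site is

$$M_{eq} = \frac{E_d}{1 + E_d - E_m},$$

and the expected beta approaches it geometrically with factor
$(E_m - E_d)$ per step. `estimate_rates()` inverts this equation for
site-specific rates given observed equilibria (e.g. the oldest sample of a
dataset), drawing the fixed side uniformly inside validity limits
(defaults $0.95 < E_m \le 1$, $0 \le E_d < 0.23$; the narrower
$0.97/0.05$ region is available as `rate_limits(0.97, 1, 0, 0.05)`).
Degenerate equilibria (0 or 1) short-circuit to $E_d = 0$ or $E_m = 1$; a
perfectly maintained site ($E_m = 1, E_d = 0$) has an undefined
equilibrium and is flagged `NA` rather than given a number.

Cells within a feature are exchangeable, so the methylated count is
advanced with its exact aggregate distribution
$\mathrm{Bin}(m, E_m) + \mathrm{Bin}(N - m, E_d)$ instead of $N$ literal
coin flips; a per-cell Bernoulli reference implementation is kept as a
test oracle and agrees in mean and variance. Population initialization
rounds half-up (with a $10^{-9}$ epsilon against floating-point
representation), affecting at most one cell per feature.

### Sampling schemes: trajectory vs independent

`simulate_methylation_dataset()` supports two designs, and the distinction
matters quantitatively:

* **trajectory** (default): each replicate set is *one* population
  advanced step by step, with the bulk level recorded at every age
  0..99. Samples within a set share their noise history, so a
  random-walk component accumulates along the trajectory. This is the
  design whose benchmark numbers match the published single-cell results:
  validation $R^2 \approx 0.996$ at $E_m = E_u = 99.9\%$ and
  $\approx 0.75$ at $99.995\%$, and an accuracy plateau of
  $R^2 \approx 0.99$ from about 32 features.
* **independent**: every sample is simulated from the ground state with
  its own noise (as bulk mode does). Removing the shared walk makes
  clocks noticeably more accurate at very high maintenance
  ($R^2 \approx 0.99$ at $99.995\%$) — useful as a contrast, and the
  configuration under which a uniform 0.51 ground state (equilibrium at
  0.5, 2000 features) yields validation $r \approx 0.94$ while an exact
  0.5 start yields none.

The marginal distribution of a sample at age $t$ is identical under both
schemes; only the within-set correlation differs. That one design choice
moves the high-maintenance benchmark from 0.99 to 0.75 is itself a useful
caution about simulation-based clock benchmarks.

### Event-based variant

`gillespie_dataset()` replaces uniform time steps with exponential waiting
times: each cell-site is a two-state continuous-time chain with switch
rates (defaults 0.1 both ways, `tmax = 5`), observed along an evenly
spaced grid per replicate population. Because the chain is memoryless,
evolving segment-wise between observation times is exact. `nrmax`
(default 8000) caps events per site trajectory — a safety bound that never
binds at the default rates. Observation times are min–max rescaled onto
the reporting age range; this affects no correlation. A clock trained on
event-based data predicts held-out observation times with $r > 0.9$,
confirming the step-based results are not an artifact of discrete time.

## Clock construction

`train_clock()` fits an elastic net with k-fold cross-validation over a
mixing-parameter grid (`l1_ratio`, default 0.1–0.9) and either an
automatic penalty path or a fixed penalty grid (`alphas`, named after the
corresponding scikit-learn argument so published settings carry over; the
one-sample-per-age human-style design uses `alphas = 1`). Folds default
to 5 with an explicit, stored shuffle seed. Features are not standardized
internally — simulated features share the $[0,1]$ scale, and this matches
the reference behavior of the Python implementation the field uses.
Sparsity (exact zero coefficients) is expected output, and the
nonzero count is recorded in `training_meta`.

Age transforms are first-class and invertible: identity; min–max scaling
of training ages to $[0,1]$ then $\times 400 - 120$ (bounds fitted on the
training ages and stored in the model so validation uses identical
scaling); $\times k$ (default 2, the transcriptomic rescaling); the
relative-age transform $-\log(-\log(a/\mathrm{maxage}))$ with inverse
$\exp(-\exp(-x))$ returning relative age in $(0,1)$ (relative ages are
clipped to $[10^{-6}, 1-10^{-6}]$ at the boundary); and the piecewise
log-linear year-scale transform used by published pan-tissue clocks
(knot at `adult_age = 20`), needed to apply published coefficient tables.
`load_clock_coefficients()` reads any feature/coefficient table with an
optional intercept row; `write_clock()`/`read_clock()` serialize models as
the same TSV dialect with transform parameters in reserved rows.

## Preprocessing

`binarize_expression()` implements the binarized-transcriptome encoding:
per sample, log10(count + 1), min–max normalization over genes, then 1 for
genes strictly above the per-sample median computed with raw zeros masked,
0 otherwise (ties binarize to 0; masking applies only to the median, not
to the comparison). Genes zero in all samples are dropped after
normalization. Transcriptomic aging simulations start from such a
binarized sample — every feature sits at a bound, which is why per-step
noise as small as 0.01 carries signal — with ten samples per time step
over ages 1–16.

`celltype_adjust()` removes cell-type-composition variance: per feature,
the residuals of beta ~ fractions (intercept included) are added back to
the feature mean and clipped to $[0,1]$. Means are preserved exactly
wherever the clip does not bind. Because fractions sum to ~1, the design
is singular as a parameterization but not as a projection; residuals are
computed by projection, identical-fraction inputs reduce to a no-op, and
only genuinely duplicated cell-type columns are rejected.
`covariate_regression()` is plain OLS with t-based two-sided p-values, the
form used for `Age ~ PredictedAge + CellTypeFractions` and for
intervention interaction models with binary group indicators.

## Evaluation conventions

`score_predictions()` reports the two-sided Pearson correlation and
$R^2 = 1 - SS_{res}/SS_{tot}$ of predictions against truth — the
coefficient of determination of out-of-sample predictions, *not* a squared
correlation; it is negative for predictors worse than the mean.
`permutation_control()` permutes sample ages against fixed predictions to
produce the empirical null of $r$ (centered at zero under
exchangeability). `clock_sweep()` repeats the simulate–train–validate
experiment over a grid of one parameter with per-replicate child seeds;
identical specs and seeds reproduce tables exactly.

## Problem sizes and reproducibility

The benchmark suite uses the published designs: 2000-feature ground
states, six replicate sets (one sample per age, 100 ages), 3 train / 3
validate, 500 features and 1000 cells for the single-cell benchmarks,
with medians over three root seeds; feature sweeps use 10 replicates for
small feature counts and 3 otherwise, on reduced grids around the values
of interest. One root seed drives everything; per-set and per-replicate
child streams are derived from it, so any replicate set can be regenerated
in isolation.

## What the generators do and do not emulate

The synthetic beta-matrix fixture draws bimodal beta-distributed values
with constant precision, so variance shrinks toward the 0/1 extremes as in
biological methylation data, and ships a young/old sample pair produced by
running the methylation simulator forward — giving `estimate_rates()` a
self-consistent target. Real data differ in ways the simulators
deliberately omit: no correlation structure between features (noise is
i.i.d. per feature), no cell-type mixture within a simulated sample, no
array/batch artifacts, no genomic-context dependence of rates, and no
hemimethylation or allele-resolved states (alleles can be represented as
separate features). Passing benchmarks therefore show that stochastic
accumulation *suffices* to build clocks under these idealized conditions;
they do not show that real clocks measure nothing else.

## Known limitations

* The reproducibility of individual elastic-net coefficients across
  independent trainings is moderate at benchmark scale (Pearson ~0.55
  over all coefficients, ~0.7 over jointly selected ones at the headline
  noise level): with 300 samples and 2000 correlated features the fit is
  strongly regularized and feature selection is unstable, even though the
  coefficient *geometry* (sign vs ground-state position) and the
  prediction accuracy reproduce tightly. Conclusions should rest on
  predictions, not on individual coefficients.
* The logit-mode and clamped-mode headline noise levels are plateau
  choices, not uniquely determined values; accuracy within the plateau
  varies by ~0.01 in $r$.
* Published-clock application (coefficient tables with year-scale
  transforms) is implemented and tested on toy tables; shipping real
  published tables is out of scope, so those checks require the user to
  supply the table.
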