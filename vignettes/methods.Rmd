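---
title: "Methods: two-stage modelling of heat-attributable mortality from climate indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage modelling of heat-attributable mortality from climate indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Summer heat kills, and how much it kills varies strongly from year to year.
`heatlag` implements a two-stage analysis that first quantifies that burden
and then asks whether it is predictable months ahead from large-scale
climate teleconnections:

1. **Stage 1** estimates, for each summer (May–September), the fraction of
   all-cause mortality attributable to heat (AF) from daily death counts
   and mean temperatures, using a time-varying distributed lag nonlinear
   model (DLNM).
2. **Stage 2** regresses the resulting annual AF series on the monthly
   curves of seven climate indices (AMO, SOI, AO, NAO, ONI, PDO, PNA) over
   a 16-month lag window, with a scalar-on-function linear model estimated
   by component-wise gradient boosting, which also performs variable
   selection among the indices.

Because real city-level mortality series of this kind are not freely
redistributable, the package ships a synthetic-data generator with a known
exposure-lag-response surface and a known index-to-heat link, so every
estimator can be validated against ground truth.

# Stage 1: the time-varying DLNM

## Model

Daily deaths $Y_t$ are modelled by quasi-Poisson regression,

$$\log \mu_t = \alpha + \mathrm{cb}(x_t, \dots, x_{t-10})^\top(\theta + s_t\,\gamma)
  + \text{dow}(t) + f_{\text{trend}}(t) + f_{\text{season}}(t),$$

where `cb` is the cross-basis of temperature and lag, $s_t$ is the date
scaled affinely to $[-0.5, 0.5]$ over the study period, and $\gamma$ is the
interaction block letting the exposure-response surface drift linearly in
time (long-term adaptation).  Controls are a day-of-week factor, a natural
cubic spline of date with one degree of freedom per decade (rounded up) for
the long-term trend, and a natural cubic spline of day-of-season with 4 df
for within-season seasonality.  The overdispersion scale is estimated from
Pearson residuals and inflates the coefficient covariance.

The cross-basis combines

* **temperature dimension**: quadratic B-spline, interior knots at the 50th
  and 90th percentiles of the pooled May–September temperature distribution
  (the percentile reference sample is the whole study period of the area,
  the convention of the DLNM literature), boundary knots at the observed
  range, no intercept;
* **lag dimension**: natural cubic spline over lags 0–10 days with two
  interior knots equally spaced on the log-lag scale
  ($10^{1/3} \approx 2.15$ and $10^{2/3} \approx 4.64$), with intercept.

Knots are *placed* on the log scale but the basis is evaluated on the
original lag scale; this concentrates flexibility at short lags where heat
effects change fastest.

## Season boundaries

Exposure histories never cross the September-to-May gap.  The first ten
days of each season take lagged temperatures by constant extrapolation of
the season's first observed value, rather than dropping 6.5 % of days.  The
synthetic-data generator mirrors the issue from the other side: it
simulates a 10-day pre-season temperature burn-in so that the *generative*
exposure history of early-May days is fully defined.  The small mismatch
between the two conventions affects only the first days of May, where the
lag-weighted heat effect is near zero.

## MMT and attributable fractions

The overall cumulative exposure-response curve is extracted on 1 July of
each year (base coefficients plus scaled-date times interaction block); the
minimum-mortality temperature (MMT) is its argmin on a 0.1 °C grid,
constrained to lie between the 10th and 90th percentile of summer
temperature — computed on the whole period, as are the fixed heat-day
thresholds.  Ties break toward the lower temperature, so the argmin is
reproducible.

Daily AFs use the backward perspective:
$\mathrm{AF}_t = 1 - \exp\{-\sum_{l=0}^{10}\eta(x_{t-l}, l)\}$ with the
fitted lag-specific log relative risk $\eta$ at date $t$'s effective
coefficients, referenced to the year's MMT.  Annual AFs sum
$\mathrm{AF}_t\,Y_t$ over *heat days* (strict exceedance of the threshold)
and divide by the year's total summer deaths.  Four heat-day definitions
are kept: the year-specific MMT and the whole-period 95th, 97.5th and 99th
temperature percentiles; the AF reference is the MMT for all four, since
AF is conventionally measured against minimum risk while the threshold
only selects which days count.  When all fixed thresholds exceed the MMT
the heat-day sets are nested, so the point estimates satisfy
$\mathrm{AF}(p99) \le \mathrm{AF}(p97.5) \le \mathrm{AF}(p95)$.

Uncertainty comes from empirical confidence intervals: coefficient vectors
are drawn from the multivariate normal approximation $N(\hat\beta, \hat V)$
(eigenvalues of $\hat V$ floored at zero if needed), and the *entire*
downstream pipeline — year-specific constrained MMTs, heat-day sets under
the MMT definition, daily and annual AFs — is recomputed per draw;
percentile 2.5/97.5 bounds are reported.  Re-solving the MMT constraint per
draw matters: it is what lets the interval reflect reference-point
uncertainty.

# Stage 2: scalar-on-function regression by boosting

## Model

For year $i$, the annual AF is modelled as

$$\mathrm{AF}_i = \sum_{j=1}^{7} \int_0^{16} \beta_j(l)\, x_{ijl}\, dl
  + s_i + \varepsilon_i,$$

where $x_{ijl}$ is index $j$'s monthly curve over lags $l = 0$ (May of
year $i$) back to $l = 16$ (January of year $i{-}1$), and $s_i$ is a smooth
year component.  The 16-month window spans 17 calendar months; the integral
is discretized on the 17 monthly nodes by the trapezoid rule (exact for
linear curves).  Each index is z-scored over all (year, lag) cells, so the
coefficient curves are per-SD effects ("scaled" coefficients).

Each functional coefficient is expanded in a cubic B-spline with 5 interior
knots on the lag grid, reducing the integral to a linear term with design
row $\sum_l w_l x_{ijl} B_k(l)$; a second-order difference penalty controls
its smoothness.  With $n = 38$ years, 5 knots balances flexibility against
sample size.  The year component is a P-spline: dense cubic B-spline with
20 interior knots and a second-order difference penalty.  P-spline bases
use the Eilers–Marx construction (equidistant knots extended beyond the
boundary) so the penalty null space contains polynomials below the penalty
order exactly — a linear trend in AF is never shrunk.

## Estimation

The model is estimated by component-wise $L_2$ boosting: starting from the
response mean, each iteration fits every base learner to the current
residuals, adds $\nu = 0.1$ times the best one (largest residual
sum-of-squares reduction), and repeats.  Every learner's ridge scale is
solved by bisection so its hat-matrix trace equals a common 4 effective
degrees of freedom — equal-flexibility learners are required for unbiased
selection.  The stopping iteration minimizes 10-fold cross-validated
squared prediction error over iterations $0..m_{\max}$ (iteration 0 is the
offset-only model, so a pure-noise response can legitimately select the
empty model); years are assigned to folds by seeded permutation.  Only
learners ever selected have nonzero coefficients, giving implicit variable
selection.  Pointwise 95 % bands for the coefficient curves come from a
nonparametric bootstrap over years with the stopping iteration held fixed.

With a single base learner and unlimited iterations, boosting converges to
the least-squares projection onto the learner's column span; the penalty's
influence vanishes in the limit, which is why stopping early (and the CV
choice of the stopping iteration) is the actual regularizer.

## Evaluation

Predictive skill is repeated (default 20×) 10-fold cross-validated $R^2$:
each training split re-runs the full boosting *including its own inner
stopping CV* (with distinct seeds from the evaluation folds), so held-out
years influence neither coefficients nor complexity.  We report
$R^2 = 1 - \mathrm{SSE}/\mathrm{SSE}_0$ with $\mathrm{SSE}_0$ the
out-of-fold error of the intercept-only model (each fold predicted by its
training-fold mean).  Benchmarking against the cross-validated null model
rather than the in-sample total sum of squares matters at $n = 38$: the
latter imposes a negative offset of about $-0.06$ on *every* model, while
with this definition a skill-free model scores near zero (mean permuted-
response $R^2 \approx -0.04$ in the package's own tests) and a genuinely
predictive model is essentially unaffected.  Out-of-fold $R^2$ may be
negative and is reported as-is.  A sensitivity model adds the year's mean
summer temperature as an unpenalized scalar linear learner.

# The synthetic-data generator

The generator defines the study conditions under which the package
validates itself:

* **Indices**: seven mutually independent standardized AR(1) monthly
  series; the "active" index gets lag-1 autocorrelation 0.9 (a slow,
  multidecadal-type dynamic), the others 0.3.
* **Temperature**: sinusoidal annual cycle (level 8 °C, amplitude 14 °C,
  peak 20 July) plus AR(1) daily noise (SD 2.5 °C, autocorrelation 0.7),
  giving May–September means near 17–18 °C with extremes around 0–30 °C —
  the humid-continental regime of the motivating setting.  The active
  index's January–May mean shifts the whole summer by γ = 1.5 °C per SD.
* **Mortality**: negative-binomial counts (variance/mean 1.2; a
  quasi-Poisson likelihood has no generative form, and the negative
  binomial matches its variance assumption) around a baseline of 60
  deaths/day at city scale, with a mild trend, winter-peaking seasonality,
  weekday effects, and the lagged temperature effect below.
* **True surface**: the cumulative log relative risk is a C1-smooth
  J-shape — linear "hockey stick" of slope 0.02 per °C above the true MMT
  of 18 °C with a 3 °C quadratic shoulder, and a mild quadratic cold rise
  (0.003 per °C²) below it — distributed over lags 0–10 with geometric
  decay (ratio 0.6).  The cold rise and the smooth shoulder are essential:
  with a perfectly flat curve below the MMT the risk minimum is not
  identified and no estimator could recover it, and a kink at the minimum
  would systematically bias any smooth-spline argmin.  The slope
  calibration puts the true annual AF above the MMT near 2.3 %, the
  magnitude typical of city-scale summer heat mortality.
* **Stage-2 truth**: when an index is active, its true functional
  coefficient is a half-cosine over lags 0–5 months (recent winter/spring
  matter, the previous year does not).

The true link strength between a slow index and summer heat is not an
observable quantity; γ and the effect sizes were chosen once to land in a
realistic regime and are not tuning knobs.

What the generator does *not* emulate: spatial temperature fields (no
gridded data), cause-specific mortality, seasonal (within-summer)
adaptation of the risk curve, measurement error in temperature, or
dependence among indices.  Passing tests therefore demonstrate internal
statistical correctness of the estimators under a faithful generative
regime, not that real mortality data meet the model's assumptions.

# Numerical choices and degenerate inputs

* MMT grid: 0.1 °C; ties toward the lower temperature; flat curves return
  the lowest qualifying temperature with a warning.
* Temperatures outside the spline boundary are clamped to the boundary
  (with a warning for prediction grids).
* The ridge scale of each base learner is solved to |edf − target| ≤ 0.01
  by bisection on the log scale; a df target above the learner's
  unpenalized df is an error.
* Rank-deficient stage-1 designs abort with the offending block named;
  IRLS non-convergence aborts with the last deviance.
* The eCI covariance is eigenvalue-floored at zero (with a warning) before
  sampling; fewer than 100 draws triggers an "unstable percentiles"
  warning.
* All randomness is seeded explicitly; a pipeline rerun under the same
  configuration is byte-identical.

# Problem sizes in the test suite

Unit tests run on reduced problems (6–12 years, baselines of 20–30
deaths/day) chosen so each statistical check retains power while the whole
suite stays fast.  The validation suite uses the full study conditions —
38 years × 153 days at city-scale counts — with 50 replicates for
parameter-recovery and selection checks, 100 replicates at 500 coefficient
draws for eCI coverage, and 50 permutations for the null-skill check; the
acceptance script runs one complete pipeline at the default configuration.

# Known limitations

* The time-varying surface is linear in date; short-term (within-season)
  adaptation is not modelled.
* Stage-2 uses stage-1 AF point estimates; stage-1 uncertainty is not
  propagated (errors-in-response are out of scope).
* With 38 annual observations, interactions among indices are not
  estimable, and component-wise boosting at this signal-to-noise admits
  occasional spurious selections of inactive indices; the bootstrap bands,
  not the selection indicator alone, should inform interpretation.
* The AF referenced to the estimated MMT is nonnegative by construction
  under a null effect (the reference is the fitted curve's own minimum),
  a small positive bias inherent to MMT-referenced attribution.
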