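---
title: "Profile-likelihood confidence intervals for model predictions"
author: "pplik"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-likelihood confidence intervals for model predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pplik)
```

## The problem

Dynamic models of biochemical networks are calibrated from sparse, noisy
time-course data and then used to predict quantities that were never
measured: the concentration time course of an unobserved compound, a ratio
of two compounds, the height of a transient peak.  The question this
package answers is how certain such a prediction is, given the data.

The classical route -- estimate parameters, build a confidence region in
parameter space, push the region through the model -- fails in practice for
ODE models: the mapping from parameters to predictions is strongly
nonlinear, the parameter space is high-dimensional and often contains
non-identifiable directions, and no sampling scheme (MCMC, bootstrap)
covers all prediction-relevant corners of such a space reliably.  The
profile-likelihood approach inverts the problem: instead of sampling the
parameter space, it scans the one-dimensional *prediction* space and asks,
for each candidate value, how well the model can still fit the data when
forced to produce that value.

## Model class and likelihood

`pplik` works with state-space models

$$\dot x(t) = f(x(t), u(t), \theta), \qquad y(t) = g(x(t), \theta) + \varepsilon,$$

declared symbolically with `ode_model()`: states, parameters, right-hand
sides, an observation map, initial values (fixed numbers or parameters) and
optional constant or piecewise-constant inputs $u$.  Expressions are parsed
once; integration uses a stiff-capable solver (`deSolve::lsoda`) and, when
a C toolchain is available, right-hand sides are translated to C and
compiled on first use, which speeds the inner optimization loops by an
order of magnitude without changing results.  All parameters -- rates,
Michaelis constants, initial concentrations -- are assumed positive, and
all optimization is performed in log-parameter space, which is the standard
parametrization for kinetic models.

Measurement noise is additive Gaussian with known standard deviation per
data point.  Then, up to an additive constant that is dropped everywhere,

$$-2\,\mathrm{LL}(y \mid \theta) \;=\; \sum_i
  \frac{\left(y_i - F(t_i, u, \theta)\right)^2}{\sigma_i^2}
  \;=\; \mathrm{RSS}(\theta \mid y),$$

with $F = g(x(t, u, \theta), \theta)$ the model response, so maximum
likelihood is weighted least squares.  `fit_model()` minimizes the RSS by
multi-start Levenberg--Marquardt (`minpack.lm`): the model's default
parameter values (or a user start) plus Latin-hypercube draws in the log
bounds box, by default four orders of magnitude around the defaults.  Each
local run is restarted from its own solution until the deviance stops
improving, which guards against premature termination on ill-conditioned
problems.  Estimating $\sigma$ is out of scope: both bundled case studies
fix it, as typical for profile-based analyses.

## Parameter profiles

For a single parameter $\theta_j$ the profile likelihood is
$\mathrm{PL}(\theta_j) = \max_{\theta_{k \ne j}} \mathrm{LL}(\theta \mid y)$,
and the likelihood-based confidence interval at level $\alpha$ is the set
where $-2\,\mathrm{PL}$ stays within the $\chi^2_1$ quantile
$\mathrm{icdf}(\chi^2_1, \alpha)$ of the optimum $-2\,\mathrm{LL}^*$.
`profile_parameter()` implements this with the same scanning machinery used
for predictions (below).  A profile that stays below the threshold in some
direction up to the bounds box is a practical non-identifiability; the
affected interval side is flagged unbounded rather than raising an error.

## The prediction profile likelihood

A *prediction* is any scalar the model can compute,
$z = F(D_\mathrm{pred}, \theta)$ for a condition
$D_\mathrm{pred} = \{t_\mathrm{pred}, g_\mathrm{pred}, u_\mathrm{pred}\}$;
$g_\mathrm{pred}$ need not be a measured observable.  The prediction
profile likelihood is the constrained maximum

$$\mathrm{PPL}(z) \;=\; \max_{\theta \,:\, F(D_\mathrm{pred}, \theta) = z}
  \mathrm{LL}(y \mid \theta),$$

and the prediction confidence interval (PCI) collects all $z$ with
$-2\,\mathrm{PPL}(z) \le -2\,\mathrm{LL}^* + \mathrm{icdf}(\chi^2_1,\alpha)$.
This requires no identifiable parameters and no parameter confidence
region; it directly tests which predictions are compatible with the data.

### Penalized constraint and exact rescaling

Hard nonlinear equality constraints are numerically unpleasant, so the
default route (`ppl_scan(method = "penalized")`) relaxes the constraint to
a quadratic penalty: optimize
$\mathrm{RSS}(\theta \mid y) + (z - F(\theta))^2 / \mathrm{SD}_c^2$ with a
small penalty width, then convert back with the identity

$$-2\,\mathrm{PPL}(z') \;=\; -2\,\mathrm{VPL}(z) - (z' - z)^2/\mathrm{SD}_c^2,
  \qquad z' = F(\theta^*(z)),$$

which holds because the data-only RSS at the penalized optimum *is* the
constrained profile value at the response $z'$ the optimizer actually
attained.  The identity is exact (for quadratic profiles the algebra closes
in closed form; in general it follows from stationarity of the penalized
optimum), so the penalty width only influences conditioning, not
correctness.  The default width is `constraint_sd_fraction` ($10^{-3}$) of
the larger of the fitted prediction magnitude and the data scale: small
enough that the rescaling correction is benign, large enough that the
penalty does not destroy the conditioning of the least-squares step.

The direct route (`method = "constrained"`) enforces $F(\theta) = z$ by an
augmented-Lagrangian loop around the same least-squares core.  It is slower
and retained as an independent cross-check; the test suite verifies that
both routes agree pointwise on the chain model to well below the threshold
scale.

### The validation profile likelihood

A validation experiment yields a *noisy* measurement, so its outcome is
more variable than the true model response: an interval that should contain
a future measurement with error SD must be wider than the PCI.  The
validation profile likelihood optimizes
$\mathrm{RSS}(\theta \mid y) + (z - F(D_\mathrm{vali},\theta))^2/\mathrm{SD}^2$
-- the same computation as the penalized profile, with the *real*
measurement error in place of the artificial penalty width -- and
thresholding it gives the validation confidence interval (VCI).  For linear
Gaussian problems the half-widths are
$\sqrt{q_\alpha}\,\mathrm{se}$ (PCI) and
$\sqrt{q_\alpha}\sqrt{\mathrm{se}^2 + \mathrm{SD}^2}$ (VCI), which the test
suite reproduces to $10^{-4}$ relative accuracy.  The VCI always contains
the PCI; as $\mathrm{SD} \to 0$ they coincide.  A model can be rejected
when a validation measurement with error SD falls outside the VCI -- not
when it falls outside the PCI.

## Scanning: how a profile is traced

All profiles are traced by `scan_config()`-controlled outward marches from
the fitted optimum, one side at a time:

* **Warm starts.**  Each grid point's optimization starts from the
  neighboring point's optimal parameters.  This is critical both for cost
  and for smoothness of the profile.
* **Adaptive steps.**  The step size targets an increase of
  `step_fraction` (default 0.2) of the threshold per step, clamped between
  `min_step_fraction` and `max_step_fraction` of the problem scale.  The
  scale is anchored on the spread of the data, not on the fitted
  prediction, because with a non-identifiable concentration dimension the
  fitted prediction can sit at an arbitrary point of the flat manifold.
* **Stopping.**  A side ends when the profile exceeds threshold +
  `threshold_margin` (crossed), when the scan has moved
  `max_range_factor` (default 10) problem scales away without crossing,
  when `max_steps_per_side` is exhausted, or at a feasibility boundary.
  The non-crossed stops flag the side as unbounded -- the operational
  signal for practical non-observability.
* **Crossing refinement.**  With `refine = TRUE` (default) the threshold
  crossing is localized by root finding on the re-optimized profile and the
  crossing point is inserted into the grid.  Plain linear interpolation
  between grid points spaced at a fifth of the threshold leaves a relative
  error of order $10^{-3}$ in the bound, which would dominate the
  linear-Gaussian exactness the package promises; root refinement brings it
  below $10^{-6}$ at the cost of a few extra optimizations per side.
  `interval_from_curve()` itself stays a pure interpolation of whatever
  grid it is given, taking the outermost crossings when a profile is
  non-monotone (the conservative choice).
* **Feasibility versus box saturation.**  When the penalized optimizer
  cannot track the scanned value (penalty exceeding
  `feasibility_pen_factor` times the threshold), the attainable response
  has saturated.  Saturation at zero is structural -- concentrations cannot
  be negative -- and bounds the interval at the feasibility boundary
  without an unbounded flag; likewise saturation with no free parameter at
  its bound (a response pinned by model structure, e.g. an initial
  condition fixed at zero, which yields a degenerate width-zero interval).
  Saturation elsewhere *with* parameters at the box bound means the
  declared parameter ranges, not the model structure, are limiting -- the
  data do not exclude values beyond the scan, and the side is flagged
  unbounded.  One consequence worth knowing: a state close to a conserved
  ceiling (e.g. a fully phosphorylated pool) can reach the ceiling only
  with box-extreme rates, so such a side may be reported unbounded rather
  than bounded at the ceiling; the classification is conservative.

## Thresholds

`profile_threshold(alpha)` returns the asymptotic $\chi^2_1$ quantile
(2.705543 at $\alpha = 0.9$).  Where the asymptotic assumption is in doubt,
`method = "montecarlo"` generates the statistic's distribution by
parametric bootstrap: simulate data at the fitted parameters, refit,
evaluate $-2(\mathrm{PPL}(z_\mathrm{gen}) - \mathrm{LL}^*)$ by constrained
optimization, and take the empirical $\alpha$ quantile of at least 100
(default 500) replicates.  On linear problems, where the statistic is
exactly $\chi^2_1$, the bootstrap quantile agrees with the asymptotic one
within its own sampling error -- the calibration the test suite checks.

## Bands, observability, coverage, design

`pci_band()` profiles a prediction at a series of time points and
interconnects the interval bounds by cubic piecewise interpolation.  The
monotonicity-preserving Hermite variant (`monoH.FC`) is used so the
interpolated band cannot overshoot between knots; unbounded time points
break the interpolated segment.  `classify_observability()` turns a band
into the dichotomy: *practically observable* (all time points bounded)
versus *non-observable* (at least one unbounded side), listing the
offending times.  Width-zero degenerate intervals (states fixed by initial
conditions) are bounded and never offend.

`coverage_study()` verifies the frequency property
$\mathrm{Prob}\!\left(F(D_\mathrm{pred},\theta_\mathrm{true}) \in
\mathrm{PCI}_\alpha\right) = \alpha$ by simulation: per replicate, fresh
noise at the true parameters, a refit (warm-started at the jittered truth,
with a multi-start fallback whenever the deviance is implausibly large for
the data size), a profile and a membership test; in validation mode the
tested quantity is an independently drawn noisy measurement.  Per-replicate
seeds are drawn once from the master seed, so every replicate is
individually reproducible; failed replicates are excluded and reported, and
more than 10% failures invalidate the study.  Asymptotic thresholds tend to
make the intervals slightly conservative -- empirical coverage at or just
above the nominal level -- which is the expected and accepted behavior.

`design_ranking()` orders all (state, time) entries of a set of bands by
descending interval width, unbounded entries first.  Wide intervals mark
conditions weakly specified by the current data: the most informative next
measurements.  Unlike Fisher-information design criteria this requires no
linearization, which matters for strongly nonlinear cascades.

## The bundled case studies

Two synthetic systems drive all tests; both are generated in code, with
seeded Gaussian noise.

**Two-step chain** (`abc_model()`): $A \to B \to C$ with rates
$\theta_1 = 0.05$, $\theta_2 = 0.1$, initial amounts
$A(0) = \theta_3 = 1$, $B(0) = C(0) = 0$, and only $C$ observed with
$\sigma = 0.1$ -- about 10% signal-to-noise, typical of cell-biology data.
The *full* design ($t = 0, 10, \ldots, 100$) covers the saturation of $C$
and renders all three states practically observable, with far tighter
bands for the measured $C$ than for $A$ and $B$.  The *short* design
($t = 0, 2, \ldots, 20$) samples only the transient rise, leaving the
total amount -- the concentration dimension of the parameters -- free:
$\theta_3$ is practically non-identifiable, and $A(t)$ (all $t$) and
$B(t)$ ($t > 0$) acquire unbounded upper interval sides, i.e. become
non-observable, while $B(0) = 0$ stays a degenerate bounded point.  The
chain also has an exact $\theta_1 \leftrightarrow \theta_2$ swap symmetry
in the observed $C$, a useful stress test: prediction profiles for $B$ are
bimodal, and the outermost-crossing rule keeps the intervals conservative.
The analytic solution (`abc_closed_form()`) serves as the integration
oracle.

**MAP kinase cascade** (`mapk_model()`): eight states
(Raf, Raf\*, Mek, Mek\*, Mek\*\*, Erk, Erk\*, Erk\*\*) with
Michaelis--Menten kinetics and negative feedback of Erk\*\* on Raf
activation; phospho-sums Raf\*, Mek\*+Mek\*\*, Erk\*+Erk\*\* are measured
at $t = 0, 100, \ldots, 1000$ s with $\sigma = 10$ nM.  The two
consecutive (de)phosphorylation steps of Mek and of Erk share parameters
and the initial concentrations (100/300/300 nM, unphosphorylated) are
known, leaving 14 free parameters for 33 data points.  The rate values
adopt the published parameterization of this cascade model and are a
synthetic stand-in, exposed in the model object so they can be overridden;
conclusions drawn from this fixture are therefore rank-based and
order-of-magnitude (which state has the widest band, and roughly how wide),
never exact reproductions.  In this setting the widest prediction band
among the states examined belongs to Erk\*\* around the onset of the
negative feedback, while Raf\* -- essentially measured directly -- stays
narrow; measuring Erk\*\* there would be the most informative follow-up
experiment.

**What the generator does not emulate.**  Real data bring non-Gaussian and
outlier-prone noise, unknown or misestimated $\sigma$, missing values,
systematic (model-misspecification) error and between-replicate
variability.  Passing tests therefore demonstrate the statistical
correctness of the machinery under its stated assumptions -- known
Gaussian noise, correct model structure -- not robustness to violations of
them.

## Numerical choices and problem sizes

* Solver: `lsoda`, relative tolerance $10^{-8}$, absolute $10^{-10}$;
  profile optimization needs objective smoothness well below the threshold
  scale.  Solver failures raise a typed condition carrying the offending
  parameters; inside optimizations they are converted to large residuals
  and counted.
* Fitting: log-parameters; bounds four orders of magnitude around the
  defaults; 20 Latin-hypercube starts by default; seeds are mandatory
  arguments, and every stochastic routine restores the caller's RNG state.
* Scans: threshold/5 step target, margin 1.0 on the $-2\mathrm{LL}$ scale,
  200 steps per side maximum, plausibility range 10 data scales, penalty
  width $10^{-3}$, crossing refinement on.
* Desk-scale study sizes used by the test suite: 200 replicates for the
  chain-model coverage study, 500 bootstrap replicates for the Monte-Carlo
  threshold, six-point time grids for bands, and a 3-state surrogate (with
  a coarser scan and no crossing refinement) for the MAPK band study;
  these sizes resolve the statistical claims being tested while keeping
  the suite runnable on a single CPU.
* Degenerate cases: a prediction fixed by the model for all parameters
  (e.g. $B(0) \equiv 0$) yields a degenerate curve and a width-zero
  interval; a threshold of zero collapses the interval onto the optimum.

## Known limitations

* Intervals are *pointwise*: bands across time are unions of per-time
  intervals, and neighboring times are statistically dependent.  Joint
  (simultaneous) prediction regions would need a multi-dimensional profile
  and are not implemented.
* Noise standard deviations are treated as known; no error-model
  estimation.
* Positivity of all parameters is assumed (log-scale optimization); models
  with genuinely sign-free parameters need reparametrization.
* The Monte-Carlo threshold follows the standard parametric-bootstrap
  construction and is validated against the linear-Gaussian case; no
  small-sample correction beyond it is attempted.
* Only ordinary differential equations: no delays, events, dosing
  schedules or algebraic constraints.
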