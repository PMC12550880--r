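---
title: "Inferring thermal and resource-competition traits from growth experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring thermal and resource-competition traits from growth experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

Phytoplankton growth depends jointly on temperature and on the supply of
essential resources (light, nitrogen, phosphorus). A factorial growth
experiment — populations grown across a temperature gradient crossed with a
resource gradient, with replicate wells tracked by plate-reader fluorescence
— yields thousands of exponential growth-rate estimates. `thermotraits`
turns such rate tables into ecological traits:

* **resource competition traits** from the Monod model, fitted per
  population and temperature;
* **thermal tolerance traits** from a double-exponential thermal
  performance curve (TPC), fitted per population and resource level;
* **shapes** of each trait's response along the complementary gradient;
* **cross-population associations** among per-population trait summaries.

Every stage is exercised end-to-end on synthetic data with known
ground-truth traits, so the whole pipeline is testable without any
laboratory data.

# Models

## Monod resource dependence

At a fixed temperature, net specific growth at resource amount $R$ is

$$\mu(R) = \mu_{\max}\frac{R}{K_s + R} - m,$$

with gross maximum rate $\mu_{\max}$ (d$^{-1}$), half-saturation constant
$K_s$ (resource units) and intrinsic loss rate $m$ (d$^{-1}$). Three traits
derive from each posterior draw:

* affinity $\alpha = \mu_{\max}/K_s$ — competitive ability at vanishing
  resource;
* minimum resource requirement
  $R^* = m_\mathrm{tot}K_s/(\mu_{\max} - m_\mathrm{tot})$ with
  $m_\mathrm{tot} = m + m_\mathrm{ext}$ — the resource level at which net
  growth exactly balances total losses; lower $R^*$ wins equilibrium
  competition. The external loss rate $m_\mathrm{ext}$ (dilution or
  sinking, system-specific) defaults to 0.1 d$^{-1}$. When
  $\mu_{\max} \le m_\mathrm{tot}$ growth can never offset losses and the
  fit reports an infinite sentinel, flagged;
* net maximum growth rate $\mu_{\max} - m$.

Derived traits are computed per retained draw and then summarized (the
median of a nonlinear function of parameters is not the function of the
medians; a unit test demonstrates the difference on an asymmetric
posterior).

## Double-exponential thermal performance curve

Across temperature $T$, growth is birth minus death, each exponential in
temperature:

$$\mu(T) = b_1 e^{b_2 T} g(R) -
  \left[d_0 + \frac{b_1 b_2}{d_2}e^{(b_2 - d_2)T_{opt}}e^{d_2 T}\right].$$

$b_1$ is the birth rate at 0&nbsp;°C, $b_2$ and $d_2$ the exponential
temperature sensitivities of birth and death, $d_0$ a
temperature-independent loss, and the death coefficient is parameterized
through $T_{opt}$ so that the replete curve ($g = 1$) peaks exactly at
$T_{opt}$. Within one resource level the limitation factor $g$ is constant
and absorbed into the birth scale, so fits use $g = 1$.

Derived thermal traits per draw, all by root finding (`uniroot`,
tolerance 10⁻⁶ °C or tighter):

* $T_{\max}$, $T_{\min}$ — zero crossings of $\mu(T)$ above and below
  $T_{opt}$, bracketed in $(T_{opt}, T_{opt}+100]$ and
  $[T_{opt}-150, T_{opt})$; a missing sign change yields a missing value
  for that draw only;
* $T_{br}$ — thermal breadth, the width of
  $\{T : \mu(T) \ge 0.8\,\mu(T_{opt})\}$.

Grid-scan oracles at 0.001&nbsp;°C resolution verify both in the test
suite.

**Identifiability.** The curve family has a mirror mode with $b_2 > d_2$ in
which $T_{opt}$ is a *minimum*; samplers can lock into it and every derived
trait becomes undefined. Because $T_{opt}$ is defined as the temperature of
maximal growth, the support is restricted to $d_2 > b_2$. This constraint
is implied by the model's semantics rather than stated among the prior
bounds, and it matches the synthetic generator's invariant.

## Priors and sampler contract

Monod priors are truncated normals (at 0): $\mu_{\max}$ (1, 0.9) and $m$
(0, 0.7) for all resources; $K_s$ resource-specific — light (2.5, 0.7),
nitrogen (2.5, 0.9), phosphorus (0.001, 0.8), reflecting the very different
scales on which the three resources limit growth. TPC priors are weakly
informative truncated normals on the sampled parameterization
($w = b_1 e^{b_2 T_{opt}}$, the birth rate at the optimum, decorrelates the
birth scale from $T_{opt}$): $w$ (1, 1), $b_2$ (0.1, 0.1), $d_0$ (0.1,
0.5), $d_2$ (0.3, 0.3), $T_{opt}$ (27, 8) bounded to [0, 50] °C. The
observation model is Gaussian with a half-normal (sd 1) prior on the
residual sd; replicates enter as independent observations.

Every fit runs 4 chains, discards the first half of the iterations as
burn-in, pools the retained halves (20,000 draws at the study-scale 10,000
iterations per chain; reduced runs use 2,000), and reports a split-chain
$\widehat{R}$ per parameter with flagging threshold 1.05. Per-fit seeds are
derived from a master seed and the unit labels (population, temperature or
level, resource), so any single fit reproduces bit-identically in
isolation.

Two samplers implement the contract:

* **Monod fits** use JAGS (Gibbs/slice sampling), which mixes cleanly on
  this 4-parameter posterior.
* **TPC fits** use a collapsed Metropolis kernel written for this package.
  The curve is linear in $(w, d_0)$ given the shape parameters, so MH runs
  on the analytically marginalized posterior of
  $(\log b_2, \log d_2, \mathrm{logit}(T_{opt}/50), \log\sigma)$; each
  proposal draws $w$ from its conditional normal (kept when positive) and
  $d_0$ from its *truncated* conditional, with the truncation probability
  entering the acceptance ratio, which keeps the kernel exact under the
  truncated priors and mobile when the posterior piles $d_0$ on the zero
  boundary (monotone-declining, cold-adapted curves do this). Plain
  componentwise and random-walk samplers leave $\widehat{R} > 1.5$ on this
  family's curved $w$–$b_2$–$d_0$ ridge even at 10,000 iterations; the
  collapsed kernel reaches $\widehat{R} \le 1.05$ by 2,000 on
  realistic-noise data. A generic adaptive-Metropolis sampler on the full
  joint posterior is retained in the package and serves as an independent
  cross-check in the tests. Numerical guards reject parameter points whose
  linear-basis values exceed $10^6$ or whose marginal quadratic form turns
  negative — floating-point cancellation otherwise fabricates density
  spikes that trap the Laplace initializer — and $d_2$ is bounded below at
  $10^{-4}$ so the death coefficient stays finite.

Fits that qualify poorly are never silently dropped: Monod fits carry a
retention flag (observed mean growth above $m_\mathrm{ext}$ at ≥ 3 resource
levels), TPC units with growth above $m_\mathrm{ext}$ at fewer than 3
temperatures are skipped with a logged reason, and non-convergence
($\max \widehat{R} > 1.05$) is flagged on the output row. Hard units —
flat curves at strongly limiting resource levels, optima at the edge of the
measured range — do get flagged at reduced iteration counts; their
curve-level quantities ($T_{opt}$, $T_{\max}$) are typically stable even
so, and the flags are the honest report of the remaining ridge
autocorrelation.

## Trait-median exclusions

Posterior medians outside the credible experimental range are flagged
(never deleted): $T_{opt}$ outside [15, 35] °C; $T_{\max}$ more than 5 °C
above the hottest treatment (> 40 °C); $T_{\min}$ more than 15 °C below the
coldest (< 0 °C); $T_{br}$ wider than the 20 °C experimental range. Bounds
are inclusive for retention — a median exactly on a bound is kept. In
synthetic runs the $T_{\min}$ filter removes the majority of estimates
(most curves cross zero below 0 °C), mirroring why lower thermal limits are
rarely analyzable from this design.

# Growth-rate estimation

Each well's ln-fluorescence trajectory is fitted under four candidate mean
structures — line; lag then line; line then saturation; lag, line,
saturation — with breakpoints profiled over the observed time points
(conditional on breakpoints each candidate is linear, so the search is
exact least squares). AIC selects the model (AICc optional); ties break
toward fewer parameters, so noiseless exponential data yield the plain
line. The exponential-segment slope is the growth rate; at least 3 points
must support it. Readings at or below zero are floored at 0.1 RFU before
logging and flagged. On the default schedule (readings at 0 and +9 h on
days 0–4, then daily through day 7 — 13 points) with 5% multiplicative
noise, the estimator recovers true rates with median absolute error about
0.02 d$^{-1}$ across a 500-well simulation.

# Shape classification along gradients

How does a trait vary along its gradient (Monod traits vs temperature; TPC
traits vs resource level, log10-transformed for nutrients)? Parameter
uncertainty is propagated by a posterior bootstrap: per iteration, one
posterior draw is sampled independently per gradient value and a penalized
cubic regression spline is fitted through those points (mgcv, basis
dimension min(10, G−1), smoothing by GCV); 5,000 iterations at study
scale, 200–500 in tests. With three or fewer gradient values only a
straight line is fitted.

The smooth term's effective degrees of freedom (EDF) measures nonlinearity
on the scale where a straight line is 1 — the intercept is not counted.
When ≥ 80% of fits have EDF ≤ 1.6, the relationship is treated as linear:
lines are refitted to the same bootstrap samples (same draw indices) and
labelled increasing/decreasing when one slope sign reaches 70%. Otherwise
each curve's first derivative is scanned on a 200-point grid; a persistent
(≥ 2 grid steps on both sides) negative-to-positive crossing marks a U
shape, positive-to-negative a hump, no crossing a monotonic trend, and the
modal shape must reach 60% of fits — else the verdict is *uncertain*. The
two probability thresholds differ because the linear pathway has two
possible labels (null expectation 50%) while the spline pathway has four
(null 25%). Traits bounded below by zero ($R^*$, $\alpha$) use a gamma
family with log link; the log link is a modelling choice (the canonical
inverse link is unstable on these small per-fit samples).

GCV is undefined on exact fits (any smoothness interpolates noiseless
collinear points, so its EDF is arbitrary); when a straight line already
explains the points to rounding error the fit is recorded as linear
(EDF 1). A mean-species curve — one unweighted fit to the across-population
means of the per-level medians — uses the same gating and shape rules.

# Cross-population associations

Six summaries per population × resource: the lowest $R^*$ across
temperatures (log-transformed, then z-scored within resource type so the
three resources' units and magnitudes are comparable), the temperature of
that minimum ($TR^*_{min}$), the largest net-$\mu_{\max}$, and the highest
$T_{opt}$, $T_{\max}$, $T_{br}$ across resource levels — maxima and minima
taken over retained, non-excluded medians only. Natural log is used for the
z-score; the base only shifts the mean, which the z-score removes.

Analyses on the summary table: PCA on centered and scaled columns (listwise
deletion, counts logged); ANOSIM (vegan, Euclidean distances, seeded
permutations) for phylum and resource grouping; Welch's ANOVA with a
hand-implemented Games–Howell post hoc (unequal-variance $t$,
Welch–Satterthwaite df, studentized-range calibration — no installed
package provides it); Kendall's tau-b matrix with two-sided p-values and no
multiple-testing correction by default (a Benjamini–Hochberg switch is
available through `p.adjust` if wanted); and an F-test of the
trait × resource interaction that gates pooling regressions across
resources.

Correlations with $T_{\max\max}$ need care: traits that can only occur
below a population's thermal maximum (e.g. $TR^*_{min}$) correlate
positively with it under pure random placement. The constrained-resampling
null draws each population's surrogate trait uniformly between a lower
bound and its $T_{\max\max}$ and records the Kendall tau across
populations; the observed tau is scored as a mid-rank percentile of that
null (tau is discrete at these sample sizes, so ties are split to keep the
percentile calibrated — it passes a uniformity check under the null in the
test suite). The default lower bound is the 15 °C experimental minimum
because lower thermal limits are mostly unestimable; estimated $T_{\min}$
can be supplied where retained.

# The synthetic-data generator

The generator emulates the study design: 19 populations × 3 resource
experiments (8 levels each; light 1–240 µmol photons m⁻² s⁻¹, nitrogen
0.5–800 µmol L⁻¹, phosphorus 0.01–50 µmol L⁻¹) × 6 temperatures (15, 20,
24, 28, 32, 35 °C) × 4 replicates — 3,648 wells per resource, 10,944 in
all. Ground truth couples the double-exponential TPC to Monod resource
dependence through $g(R) = R/(K_s + R)$; the coupling form is chosen so
the synthetic surface is self-consistent with the fitted models. Per
population, traits are drawn from seeded ranges a limnologist would call
realistic for temperate lake phytoplankton: $T_{opt}$ 18–33 °C, replete
peak growth 0.6–1.8 d$^{-1}$, $d_2 > b_2$ by 0.08–0.25 °C⁻¹, $K_s$
spanning orders of magnitude with resource-specific scales.

Two observation pathways: a fast path adds Gaussian noise (sd 0.05
d$^{-1}$ by default) directly to the true rate surface; the raw path
simulates fluorescence trajectories — flat at the 20-RFU inoculum for the
lag, exponential at the true rate, hard-capped at the population's
carrying capacity (300–900 RFU), floored at 0.1 RFU — under multiplicative
lognormal noise (CV 0.05) on the 13-point reading schedule.

What the generator does *not* emulate: plate-position effects, bacterial
contamination, pigment-channel differences between phyla, acclimation
carry-over, and any real covariance structure among traits across
populations (traits are drawn independently). Passing tests therefore
demonstrate that the pipeline recovers what this generative model encodes
at realistic noise; they cannot certify behavior under the correlated
biological and technical structure of real plates.

# Problem sizes and numerical choices in the tests

The test suite and the acceptance script use reduced but non-trivial
sizes chosen to finish comfortably on a single CPU: samplers at 4 × 2,000
iterations (4,000 pooled draws), 20-fit recovery batches, 200-member
bootstrap ensembles, derived-trait root finding thinned to at most a few
hundred draws per fit, and a 6-population three-resource end-to-end study.
Monod recovery is evaluated at truth consistent with the informative priors
($\mu_{\max}$ 1.5, $K_s$ 2.5 — the nitrogen prior mean, $m$ 0.1): with
$K_s$ far from the prior mean the prior's shrinkage dominates the error at
5% rate noise (least squares does no better than ~8–13% there), so
prior-consistent truth is the setting in which recovery measures the
sampler rather than the prior — the standard simulation-based-calibration
convention. Other constants: bisection/uniroot tolerances 10⁻⁸–10⁻¹⁰,
exclusion bounds as above, seeds derived everywhere from a single master
seed via a string-labelled hash so stages and single fits replay
independently.

# Known limitations

* The TPC posterior keeps a weakly identified $b_2$–$d_0$–$d_2$ ridge;
  at reduced iteration counts a minority of hard fits (flat or
  edge-of-range curves) exceed the 1.05 flag and are reported as such.
* $T_{\min}$ is usually unestimable from a 15–35 °C design (the zero
  crossing extrapolates far below the coldest treatment); downstream
  analyses use it only as an optional null-model bound.
* The gamma-family bootstrap occasionally fails to converge on extreme
  draws; such fits are skipped and the ensemble size is reported.
* Replicates are pooled as independent observations; a hierarchical
  replicate model is out of scope.
* The pipeline fits Monod per temperature and the TPC per resource level;
  no joint temperature × resource response surface is fitted.
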