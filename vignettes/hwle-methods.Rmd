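---
title: "Estimating healthy working life expectancy with hwle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating healthy working life expectancy with hwle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwle)
```

## The problem

Healthy working life expectancy (HWLE) is the expected number of years a
person can expect, from age 50, to spend simultaneously *healthy* (no
limiting long-standing illness) and *in paid work*. It is estimated from
longitudinal ageing surveys in which health and work status are observed only
at interviews roughly two years apart, while death ages are known exactly
from register linkage. `hwle` implements the full estimation pipeline for
this design: a continuous-time multi-state survival model for the panel data,
integration of the fitted model into state expectancies, and multiple
imputation for item-missing interview data.

The default state structure (`hwle_states(3)`) has states

1. **HW** — healthy and in work,
2. **nHW** — not healthy and/or not in work (a single pooled state),
3. **dead** (absorbing),

with permitted transitions 1↔2, 1→3, 2→3. The recovery arrow 2→1 matters:
a raised exit hazard from HW does not by itself imply lower HWLE, because
people return to healthy work; expectancies must therefore be computed from
the full process, not read off the hazards. A 5-state variant
(`hwle_states(5)`) splits nHW into the three remaining health-by-work
combinations for sensitivity analyses.

## Transition-intensity model

For each permitted transition $r \to s$ the intensity at age $t$ given binary
covariates $x$ is Gompertz-type log-linear:

$$ q_{rs}(t, x) \;=\; \exp\!\Big\{ \log q^0_{rs} + \beta^{\mathrm{age}}_{rs}\,(t - 50)
   + \textstyle\sum_k \beta_{rs,k}\, x_k \Big\}. $$

* $q^0_{rs}$ is the baseline intensity **at age 50** (per year);
* $\exp(\beta^{\mathrm{age}}_{rs})$ is the per-year-of-age hazard rate ratio;
* $\exp(\beta_{rs,k})$ is the covariate's age-adjusted hazard rate ratio
  (aHRR) on that transition.

Age is always included on every transition. Covariate effects can be
constrained to HRR = 1 on selected transitions (`fix_hrr()`); the canonical
use is workplace factors on transitions *out of* nHW, where the factor is
undefined because nHW occupants need not be working. `fix_age` additionally
permits the time-homogeneous submodel, used for closed-form validation.

Covariates enter at their value at the **start** of each observation
interval and are treated as piecewise-constant between interviews. This is
the convention the data support — time-varying covariates are only seen at
interviews — and it is the model's main approximation for fast-moving
covariates.

## Panel likelihood

Subjects contribute one factor per pair of consecutive observations:

* **alive → alive**, states $r$ at $t_0$ and $s$ at $t_1$:
  $P_{rs}(t_0, t_1)$, the interval transition probability;
* **exact death** at $t_d$ after being in $r$ at $t_0$: the state just
  before death is unknown, so the contribution integrates over it,
  $\sum_{s\ \mathrm{alive}} P_{rs}(t_0, t_d)\, q_{s,\mathrm{dead}}(t_d)$.

$P(t_0, t_1)$ is computed by splitting the interval into sub-intervals no
longer than `step` (default 0.5 years), evaluating the generator $Q$ at each
sub-interval **midpoint** age, and composing the matrix exponentials.
Midpoint evaluation makes the piecewise-constant approximation second-order
accurate in `step`; against a high-accuracy solution of the Kolmogorov
forward equations $\mathrm{d}P/\mathrm{d}t = P\,Q(t)$ the chaining agrees to
better than $10^{-6}$ per entry at `step = 0.01` (tested on randomized
3-state instances), and halving the default step moves expectancies by well
under 0.005 years. Because death is absorbing, only the alive-state block is
propagated (closed form for one or two alive states, scaling-and-squaring
for more), and the death-state probability is the row deficit — which keeps
rows summing to one exactly.

Two numerical guards are worth stating. Intensities are capped at $10^8$ per
year *identically* in the generator and in the exact-death density factor;
an inconsistent cap would let extreme trial parameters inflate the density
term faster than its matching survival penalty and create spurious optima.
And the 2×2 exponential is evaluated from $\exp(s \pm d)$ with both
eigenvalues non-positive, so it cannot overflow even under wild parameter
draws in the uncertainty stage. Observation sequences that are impossible
under the transition mask yield a log-likelihood of $-\infty$ rather than an
error, so the optimizer can back away from them.

## Maximum likelihood

`fit_msm()` maximises the likelihood by BFGS (relative tolerance $10^{-10}$)
from crude-rate starting values (observed transition counts over person-time,
zero slopes), then applies up to two Newton steps with a finite-difference
Hessian; at a smooth optimum this polish reaches the closed-form solution to
near machine precision — on time-homogeneous alive/dead data the fitted rate
matches deaths ÷ person-time to about $10^{-10}$ relative error. The
covariance is the inverse negative Hessian at the optimum; Wald intervals
use $z = 1.96$ on the log scale, matching the usual aHRR reporting.
Non-convergence (optimizer failure, or a Hessian that is singular or not
positive definite) is reported through a `converged` flag rather than an
error, because the multiple-imputation stage must be able to drop failed
fits when pooling. With very few observed transitions of some type — death
directly from HW is genuinely rare in this design — the corresponding
baseline and slope are weakly identified; the fitter warns when a transition
has fewer observations than free parameters.

## From hazards to expectancies

State occupancy from age 50 is propagated over an age grid with step `h`
(default 0.25 years) by chaining interval probabilities, holding the
covariate profile fixed over age (time-independence in the expectancy stage,
even for covariates fitted as time-varying). Expected years in state $s$ are
the trapezoidal integral of its occupancy curve up to `max_age = 120`; the
occupancy mass still alive at 120 contributes no further years, a hard
truncation that is numerically irrelevant at these mortality levels.
Trapezoidal integration matches the $O(h^2)$ accuracy of the occupancy
chaining itself.

Marginal (population-level) expectancies weight the per-starting-state
expectancies by an initial-state distribution at age 50, estimated by
logistic regression of the baseline state on baseline age evaluated at 50
(one-vs-rest, normalised, for the 5-state space). Total life expectancy is
the sum of the alive-state expectancies, so the decomposition

$$\mathrm{HWLE} + \text{(years nHW)} = \mathrm{LE}$$

holds *exactly* (to floating point, tested at $10^{-8}$) by construction.

Confidence intervals come from parametric simulation of the estimator:
`n_draws` (default 1000) parameter vectors from
$N(\hat\theta, \widehat{\mathrm{Cov}})$, expectancies recomputed per draw,
2.5/97.5 percentiles reported. A covariance that fails positive
semi-definiteness is repaired by clipping negative eigenvalues at zero, with
a warning. The seed is a required argument: intervals are Monte-Carlo and
must be reproducible. The initial-state weights are held at their point
estimate across draws; their sampling error is small relative to the
parameter uncertainty at these sample sizes, but the intervals do not
account for it.

## Missing interview data

Item missingness (health/work state or covariates at an interview) is
handled by multiple imputation with predictive mean matching (PMM) on the
wide, all-waves-simultaneously matrix: each incomplete variable-wave column
is regressed on every other column, baseline age and user-supplied auxiliary
variables among its complete cases; coefficients are perturbed by a proper
posterior draw per imputation; and each missing cell receives the observed
value of one of `donors` (default 5) nearest complete cases by predicted
value. Because donors are observed values, imputed binary covariates stay in
{0, 1} and imputed states stay valid codes. Chained passes run for `cycles`
(default 10) visits in fewest-missing-first order; `M` (default 20)
completed datasets are produced. Cells that are structurally absent — after
death or censoring — are never imputed; inside the chained regressions they
are filled by last-observation-carried-forward (then column means) purely to
serve as predictors, and those fills never reach the output.

Each completed dataset is fitted separately (`run_per_imputation()`), failed
convergences are flagged, and results are pooled by Rubin's rules over the
converged fits only: pooled point = mean, total variance = within +
$(1 + 1/m)\,\times$ between, reference $t$ degrees of freedom by the
Barnard–Rubin formula (reducing to $(m-1)/\lambda^2$ at infinite
complete-data df, the default here given the cohort sizes). Hazard rate
ratios are pooled on the log scale and exponentiated — the pooled HRR is the
geometric mean of the per-imputation HRRs — while expectancies are pooled on
the raw years scale, with each imputation's Monte-Carlo draw variance as its
within-imputation variance.

## The synthetic cohort generator

Because the motivating survey microdata are access-restricted, the package
carries a first-class generator (`simulate_cohort()`) whose pinned default
scenario (`inst/extdata/scenarios/elsa_like.yaml`) emulates the design of an
English ageing survey:

* five interview waves, nominally 2 years apart with ±0.25 years of uniform
  jitter; ages 50+ at entry, baseline ages drawn from bands with weights
  0.30/0.32/0.25/0.12/0.01 across 50–60 … 90–100;
* baseline state from a logistic law in age (intercept −0.2, slope −0.05
  per year above 50), chosen so that about 27% of the cohort is
  healthy-and-working at baseline, declining with age;
* generating intensities $q^0 = (0.100, 0.001, 0.450, 0.0035)$ for
  1→2, 1→3, 2→1, 2→3 with per-year age HRRs (1.07, 1.06, 0.86, 1.10).
  The age HRRs sit at published values for this model class, and the
  baselines were calibrated once, by occupancy integration of the generating
  model, so the implied marginals from age 50 (HWLE ≈ 9.1 years, LE ≈ 31.4
  years) sit near published national magnitudes; they were then frozen;
* five binary covariates with baseline prevalences 0.28/0.24/0.25/0.24/0.37
  (pain interference, osteoarthritis, mental health problems, obesity,
  physical inactivity) evolving by first-order wave-to-wave onset/recovery
  flips; pain carries the single generating effect, HRR 1.5 on 1→2, with
  the other transitions fixed at 1;
* an auxiliary response-propensity proxy correlated with pain, available to
  the imputation stage;
* exact death ages, simulated by competing-risks sampling on a monthly
  piecewise-constant rate grid (matching month-resolution age construction
  in such surveys; exact inversion of the Gompertz integral would be
  possible but the monthly grid is simple and testably convergent).

Under this scenario, refitting recovers the generating parameters with
close-to-nominal 95% Wald coverage across 50 replicates of n = 2000 —
slightly conservative for the mortality baselines, whose intervals inherit
width from the weakly identified HW→death route — and the marginal HWLE
reproduces the generating model's integrated truth within Monte-Carlo error
(the acceptance suite runs exactly this study).

The missingness injector supports MCAR and a MAR mechanism in which the
probability that a covariate is missing at an interview depends on the
auxiliary indicator and the subject's status at the *following* observation,
with an interaction — all observed quantities, so the mechanism is MAR, but
the outcome-dependence makes complete-case analysis biased for the
covariate's HRR while imputation using all waves is not. This construction
is deliberate: it is the regime in which multiple imputation demonstrably
beats complete-case analysis, and the package's tests verify exactly that
ordering. It is a stylised mechanism; real survey non-response is not
claimed to follow it.

What the generator does **not** emulate: survey weights, household
clustering, calendar-time effects, misclassification of self-reported
states, correlated covariate dynamics, or informative wave non-response
beyond the stylised MAR mechanism. Passing the recovery studies therefore
shows the estimator is correct for its model class, not that the model class
captures every feature of real survey data.

## Study sizes used in the test suite

The simulation studies are sized to be informative while keeping the suite
quick to run routinely: parameter recovery uses the scenario default of 50
replicates at n = 2000 with the fits warm-started at the generating values
(the optimum is the same; the warm start only shortens the search), the
imputation comparison uses 20 replicates at n = 800 with M = 5 imputations,
and the interval-coverage study uses 100 small alive/dead cohorts. The
acceptance script re-runs the single-cohort pipeline end to end at the
default n = 2000.

## Known limitations

* Covariate values are carried from the interval start; rapidly-changing
  covariates are therefore smoothed, and their aHRRs attenuate toward the
  null — a property of the design, not fixable by the estimator.
* The initial-state regression conditions only on age; marginal HWLE for
  populations whose baseline state depends on other covariates needs an
  explicit initial distribution.
* Baseline hazards for rare transitions (death directly from HW) are weakly
  identified at realistic sample sizes; expectancies are insensitive to
  this because those deaths are few, but the corresponding aHRR intervals
  are very wide, and individual imputed datasets can fail to converge — the
  pooling stage is built to tolerate that.
* Expectancy intervals ignore initial-state-weight uncertainty, and the
  5-state preset takes the general matrix-exponential path, which is slower.
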