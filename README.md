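# hwle — healthy working life expectancy from multi-state models

`hwle` estimates **Healthy Working Life Expectancy (HWLE)**: the expected
number of years, from age 50, spent simultaneously *healthy* (no limiting
long-standing illness) and *in paid work*. It is aimed at researchers
analysing longitudinal ageing surveys in which health and work states are
observed only at interviews every couple of years while death ages are known
exactly from register linkage — the classic panel-data multi-state design.

The package implements the full pipeline:

* a continuous-time 3-state model (healthy-and-working `HW` ↔ not-healthy
  and/or not-working `nHW`, both → dead; a 5-state variant splits `nHW`)
  with Gompertz-type log-linear transition intensities

  $$q_{rs}(t, x) = \exp\{\log q^0_{rs} + \beta^{age}_{rs}(t-50) + \textstyle\sum_k \beta_{rs,k} x_k\},$$

  fitted by maximum likelihood on interval-censored state observations with
  exact death ages (the state just before death is integrated out), and
  reported as age-adjusted hazard rate ratios `exp(β)` with Wald intervals;
* per-transition constraints (`fix_hrr()`), e.g. workplace factors fixed at
  HRR = 1 on transitions out of `nHW`, where non-workers make the factor
  undefined;
* ELECT-style expectancy integration: state-occupancy probabilities
  propagated over an age grid from 50 to 120 and integrated to HWLE, years
  not-healthy-and/or-not-working, and total life expectancy
  (LE = HWLE + non-HW years holds exactly by construction), with
  simulation-based 95% intervals;
* multiple imputation of missing interview items by predictive mean matching
  across all waves, with Rubin's-rules pooling and Barnard–Rubin degrees of
  freedom, tolerant of per-imputation convergence failures;
* a synthetic ELSA-like cohort generator with known ground truth
  (`simulate_cohort()`), used to validate the whole pipeline by parameter
  recovery.

## Worked example

Simulate the default synthetic cohort (2,000 subjects, five 2-yearly waves,
~27% healthy-and-working at baseline), fit the age-only 3-state model, and
integrate expectancies from age 50:

```r
library(hwle)

panel <- simulate_cohort("elsa_like", seed = 1)
fit   <- fit_msm(msm_spec(hwle_states(3)), panel)
hazard_ratio_table(fit)[, c("transition", "effect", "formatted")]
#>   transition effect        formatted
#> 1     HW-nHW    age 1.07 (1.06,1.08)
#> 2    HW-dead    age 0.94 (0.74,1.21)
#> 3     nHW-HW    age 0.86 (0.84,0.88)
#> 4   nHW-dead    age 1.10 (1.09,1.11)

init <- initial_state_distribution(panel, at_age = 50)
expectancy_uncertainty(fit, init, n_draws = 500, seed = 2)
#> Expected years from age 50 (95% simulation intervals, 500 draws):
#>  state           formatted
#>     HW    7.99 (7.38,8.49)
#>    nHW 23.38 (21.78,24.25)
#>     LE 31.37 (29.49,32.31)
```

The age row for `HW-nHW` says each extra year of age raises the hazard of
leaving healthy work by about 7% — the generating value of the scenario.
The expectancy table says a 50-year-old drawn from this cohort's baseline
state mix can expect about 8 years healthy and in work out of a remaining
life expectancy of about 31.4 years (generating LE: 31.4; the age-only
model marginalises over the scenario's pain-interference mixture, so its
HWLE sits below the pain-free generating value of 9.07).

Covariate models follow the usual reporting layout — aHRRs per transition,
constraints where a factor is undefined, and HWLE with and without the
factor:

```r
spec <- msm_spec(hwle_states(3), covariates = "pain",
                 constraints = rbind(fix_hrr("pain", 1, 3),
                                     fix_hrr("pain", 2, c(1, 3))))
fit  <- fit_msm(spec, panel)
subset(hazard_ratio_table(fit), effect == "pain",
       c(transition, effect, formatted))
#>   transition effect        formatted
#>       HW-nHW   pain 1.32 (1.11,1.58)
#>      HW-dead   pain     1.00 (fixed)
#>       nHW-HW   pain     1.00 (fixed)
#>     nHW-dead   pain     1.00 (fixed)

tab <- expectancy_table(fit, init, data.frame(pain = c(0, 1)),
                        n_draws = 500, seed = 2)
round(tab[, c("pain", "HW_point", "HW_low", "HW_high", "LE_point")], 2)
#>   pain HW_point HW_low HW_high LE_point
#> 1    0     8.36   7.70    8.92    31.44
#> 2    1     7.16   6.36    7.81    31.23
```

The fitted pain aHRR of 1.32 (1.11, 1.58) covers the generating value 1.5,
and people with pain interference are estimated to spend 1.2 fewer years
healthy and in work from age 50.

A config-driven pipeline (`run_all()`, or the thin CLI at
`inst/scripts/hwle-cli.R`) ties simulation, validation, (optional)
imputation, fitting and expectancy export together and writes a manifest
that reproduces every output bit for bit.

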