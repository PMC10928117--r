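# Pinned default synthetic-cohort scenario: an English ageing-survey-like
# design. Five interview waves roughly two years apart from age 50+, a
# 3-state healthy-working-life structure (1 = healthy and in work, 2 = not
# healthy and/or not in work, 3 = dead), exactly observed death ages,
# baseline healthy-and-working share near 27%, and covariate prevalences
# matching published wave-2 descriptives. Generating intensities are
# calibrated so that marginal life expectancy and healthy working life
# expectancy from age 50 sit near published national estimates
# (HWLE ~ 9 years, LE ~ 31-32 years).
name: elsa_like
states: 3
n_subjects: 2000
n_waves: 5
wave_interval: 2.0
wave_jitter: 0.25
age_origin: 50
max_age: 120
step: 0.5
age_bands:          # [lower, upper, weight]
  - [50, 60, 0.30]
  - [60, 70, 0.32]
  - [70, 80, 0.25]
  - [80, 90, 0.12]
  - [90, 100, 0.01]
init_logit:         # P(healthy-and-working at baseline) on the logit scale
  intercept: -0.2
  slope: -0.05      # per year of baseline age above 50
transitions:        # baseline intensity at age 50 and per-year age HRR
  "1-2": {q0: 0.1000, hr_age: 1.07}
  "1-3": {q0: 0.0010, hr_age: 1.06}
  "2-1": {q0: 0.4500, hr_age: 0.86}
  "2-3": {q0: 0.0035, hr_age: 1.10}
covariates:
  pain:     {prevalence: 0.28, onset: 0.10, recovery: 0.25,
             hr: {"1-2": 1.5}}   # effect on other transitions fixed at 1
  oa:       {prevalence: 0.24, onset: 0.05, recovery: 0.02}
  mh:       {prevalence: 0.25, onset: 0.08, recovery: 0.30}
  obese:    {prevalence: 0.24, onset: 0.05, recovery: 0.10}
  inactive: {prevalence: 0.37, onset: 0.12, recovery: 0.20}
aux:                # response-propensity proxy, correlated with its parent
  aux_resp: {parent: pain, p_given_parent: 0.70, p_given_other: 0.25}
missingness:
  mechanism: none
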