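# Shared fixtures, all built in code at test time.

# exact-death exponential survival panel: n subjects observed from age 55,
# censored after `cens` years, death ages exact
two_state_panel <- function(n = 1500, lam = 0.1, cens = 8, seed = 2,
                            start_age = 55) {
  set.seed(seed)
  t_death <- rexp(n, lam)
  died <- t_death < cens
  d <- data.frame(
    id = rep(seq_len(n), each = 2),
    age = as.vector(rbind(start_age, start_age + pmin(t_death, cens))),
    state = as.vector(rbind(1L, ifelse(died, 2L, 1L))),
    exact_death = as.vector(rbind(FALSE, died)))
  list(panel = cohort_panel(d, two_state_space()),
       deaths = sum(died), person_time = sum(pmin(t_death, cens)))
}

# small hand-written 3-state panel (no missingness)
tiny_panel <- function() {
  d <- data.frame(
    id = rep(c("a", "b", "c"), times = c(3, 3, 2)),
    age = c(51, 53, 55,  60, 62.1, 63.5,  70, 71.2),
    state = c(1, 1, 2,  2, 1, 2,  2, 3),
    exact_death = c(rep(FALSE, 7), TRUE))
  cohort_panel(d, hwle_states(3))
}

# scenario scaled down for quick fits
small_scenario <- function(n = 400, waves = 4) {
  sc <- load_scenario()
  sc$n_subjects <- n
  sc$n_waves <- waves
  sc
}

# model spec matching the default scenario's generating structure: pain
# affects only the HW -> nHW transition, fixed at HRR 1 elsewhere
scenario_spec <- function() {
  msm_spec(hwle_states(3), covariates = "pain",
           constraints = rbind(fix_hrr("pain", 1, 3),
                               fix_hrr("pain", 2, c(1, 3))))
}

# generating truth packed under scenario_spec()'s free parameters
scenario_theta_true <- function(sc = load_scenario()) {
  gm <- hwle:::scenario_model(sc)
  spec <- scenario_spec()
  hwle:::pack_params(spec, msm_params(spec, gm$params$logq0,
                                      gm$params$beta_age, gm$params$beta))
}
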