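# Synthetic ageing-cohort generator: continuous-time trajectories from a
# known ground-truth model, panel observation at roughly 2-yearly interview
# waves, exact death ages, wave-to-wave covariate dynamics, and optional
# missingness injection for testing the imputation pipeline.

#' Load a simulation scenario
#'
#' Scenarios are YAML files pinning the generating model (state space,
#' baseline intensities, age slopes, covariate effects), the cohort design
#' (sample size, baseline age bands, wave schedule), covariate prevalences
#' and wave-to-wave onset/recovery probabilities, the baseline-state logistic
#' law, and any missingness mechanism.  The packaged default
#' (`"elsa_like"`) emulates an English ageing-survey design: five 2-yearly
#' waves from age 50+, a 3-state structure with about 27% of the cohort
#' healthy-and-working at baseline, covariate prevalences matching published
#' wave-2 descriptives, and exactly observed death ages.
#'
#' @param name packaged scenario name, or a path to a YAML file.
#' @return scenario list.
#' @export
load_scenario <- function(name = "elsa_like") {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "hwle", mustWork = TRUE)
  sc <- yaml::read_yaml(path)
  sc$path <- path
  sc
}

# scenario -> (msm_spec, msm_params) of the generating process
scenario_model <- function(scenario) {
  space <- hwle_states(scenario$states %||% 3)
  covs <- names(scenario$covariates %||% list())
  # covariates with no stated effect anywhere are prevalence-only; they are
  # not part of the generating intensity model
  eff_covs <- covs[vapply(covs, function(nm)
    !is.null(scenario$covariates[[nm]]$hr), TRUE)]
  spec <- msm_spec(space, covariates = eff_covs,
                   age_origin = scenario$age_origin %||% 50,
                   step = scenario$step %||% 0.5)
  tr <- spec$transitions
  key <- paste0(tr$from, "-", tr$to)
  logq0 <- vapply(key, function(k) log(scenario$transitions[[k]]$q0), 0)
  ba <- vapply(key, function(k) log(scenario$transitions[[k]]$hr_age), 0)
  beta <- matrix(0, nrow(tr), length(eff_covs))
  for (j in seq_along(eff_covs)) {
    hr <- scenario$covariates[[eff_covs[j]]]$hr
    for (k in names(hr)) beta[match(k, key), j] <- log(hr[[k]])
  }
  list(spec = spec, params = msm_params(spec, logq0, ba, beta),
       covariates = covs)
}

#' Ground truth implied by a scenario
#'
#' Returns the generating `msm_spec`/`msm_params` pair, the baseline-state
#' law, and the scenario's exact marginal expectancies from the starting age
#' obtained by occupancy integration under the generating parameters (the
#' quantity parameter-recovery studies are checked against).
#'
#' @param scenario a [load_scenario()] list.
#' @param covariates covariate profile for the truth computation (default:
#'   all zero).
#' @param h integration grid step.
#' @return list with `spec`, `params`, `init_probs`, `expectancies`
#'   (an `expectancy_point`).
#' @export
scenario_truth <- function(scenario, covariates = NULL, h = 0.1) {
  gm <- scenario_model(scenario)
  p1 <- plogis(scenario$init_logit$intercept)
  init <- if (gm$spec$state_space$n_alive == 2) c(p1, 1 - p1) else
    stop("scenario truth currently computed for the 3-state preset")
  exp_pt <- marginal_expectancies(list(spec = gm$spec, params = gm$params),
                                  init, covariates = covariates,
                                  start_age = scenario$age_origin %||% 50,
                                  max_age = scenario$max_age %||% 120, h = h)
  list(spec = gm$spec, params = gm$params, init_probs = init,
       expectancies = exp_pt)
}

#' Simulate one continuous-time trajectory
#'
#' Jump times are drawn by competing-risks sampling on a fine
#' piecewise-constant rate grid (monthly by default, matching
#' month-resolution age construction); the next state is chosen with
#' probability proportional to the transition intensities at the jump age.
#' The path terminates at death or `max_age`.
#'
#' @param spec,params generating model ([msm_spec()], [msm_params()]).
#' @param baseline_age,baseline_state starting age (>= age origin) and alive
#'   state.
#' @param covariate_path `NULL` (all-zero covariates), a single named
#'   profile, or a data.frame with a column `age` (segment start ages, first
#'   equal to `baseline_age`) and one column per covariate: covariates are
#'   piecewise constant between the listed ages.
#' @param max_age truncation age.
#' @param dt rate-grid resolution in years (default 1/12).
#' @return data.frame of path segments: `age` (segment entry age), `state`;
#'   the final row is the death state at the exact death age when death
#'   occurs before `max_age`.
#' @export
simulate_trajectory <- function(spec, params, baseline_age, baseline_state,
                                covariate_path = NULL, max_age = 120,
                                dt = 1 / 12) {
  stopifnot(baseline_age >= spec$age_origin)
  lay <- cpp_layout(spec)
  if (is.null(covariate_path) || !is.data.frame(covariate_path)) {
    x <- setNames(covariate_vector(spec, covariate_path), spec$covariates)
    covariate_path <- data.frame(age = baseline_age)
    for (nm in names(x)) covariate_path[[nm]] <- x[[nm]]
  }
  seg_ages <- c(covariate_path$age, max_age)
  out <- data.frame(age = baseline_age, state = baseline_state)
  s <- match(baseline_state, lay$alive) - 1L
  t0 <- baseline_age
  for (i in seq_len(nrow(covariate_path))) {
    a1 <- seg_ages[i + 1]
    if (t0 >= a1) next
    prof <- as.list(covariate_path[i, spec$covariates, drop = FALSE])
    eta <- eta_profile(spec, params, prof)
    jumps <- cpp_sim_segment(s, t0, a1, eta, as.numeric(params$beta_age),
                             lay$tfrom, lay$tto, lay$n_alive,
                             spec$age_origin, dt)
    if (nrow(jumps)) {
      st <- ifelse(jumps[, "state"] == lay$n_alive, spec$state_space$death,
                   lay$alive[jumps[, "state"] + 1L])
      out <- rbind(out, data.frame(age = jumps[, "age"], state = st))
      s <- jumps[nrow(jumps), "state"]
      if (s == lay$n_alive) break
    }
    t0 <- a1
  }
  rownames(out) <- NULL
  out
}

# state of a trajectory at a given age (right-continuous)
path_state_at <- function(path, age) {
  i <- findInterval(age + 1e-12, path$age)
  if (i < 1L) return(path$state[1])
  path$state[i]
}

#' Observe a trajectory at interview waves
#'
#' Records the state at each wave age while the subject is alive, appends an
#' exact death record at the death age when the path dies before the last
#' wave, and attaches the wave covariate values.  Subjects who fail the
#' multiple-observation rule are emitted anyway — validation drops and
#' counts them, mirroring the study's exclusion accounting.
#'
#' @param path a [simulate_trajectory()] result.
#' @param wave_ages interview ages.
#' @param covariate_waves optional data.frame (one row per wave) of covariate
#'   values recorded at the interviews.
#' @param id subject identifier.
#' @param death_state death state index.
#' @return data.frame of panel records (`id`, `age`, `state`,
#'   `exact_death`, covariates).
#' @export
sample_waves <- function(path, wave_ages, covariate_waves = NULL, id = "s1",
                         death_state = max(path$state)) {
  died <- any(path$state == death_state)
  death_age <- if (died) path$age[match(death_state, path$state)] else Inf
  keep <- wave_ages < death_age
  rec <- data.frame(id = id, age = wave_ages[keep],
                    state = vapply(wave_ages[keep], path_state_at,
                                   0, path = path),
                    exact_death = FALSE)
  if (!is.null(covariate_waves))
    rec <- cbind(rec, covariate_waves[keep, , drop = FALSE])
  if (died && death_age <= max(wave_ages)) {
    drow <- data.frame(id = id, age = death_age, state = death_state,
                       exact_death = TRUE)
    if (!is.null(covariate_waves)) {
      for (v in names(covariate_waves)) drow[[v]] <- NA
    }
    rec <- rbind(rec, drow)
  }
  rownames(rec) <- NULL
  rec
}

#' Simulate a full synthetic cohort
#'
#' Draws baseline ages from the scenario's age bands, baseline states from
#' its logistic law, baseline covariates from their prevalences, evolves
#' covariates wave to wave by first-order onset/recovery flips, simulates
#' each subject's continuous-time trajectory under the generating
#' intensities (covariates piecewise constant between waves), observes it at
#' jittered interview waves with exact death ages, and returns a validated
#' panel.  Identical seeds give identical panels.
#'
#' @param scenario a [load_scenario()] list (or scenario name).
#' @param seed integer RNG seed (required).
#' @param n_subjects optional override of the scenario sample size.
#' @return A [cohort_panel()] whose attribute `"truth"` holds the generating
#'   model (see [scenario_truth()]); auxiliary columns are included for
#'   imputation experiments.
#' @export
simulate_cohort <- function(scenario = load_scenario(), seed,
                            n_subjects = NULL) {
  if (missing(seed)) stop("'seed' is required")
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  set.seed(seed)
  gm <- scenario_model(scenario)
  spec <- gm$spec
  sp <- spec$state_space
  n <- n_subjects %||% scenario$n_subjects
  if (n < 1) stop("n_subjects must be >= 1")
  W <- scenario$n_waves %||% 5
  iv <- scenario$wave_interval %||% 2
  jit <- scenario$wave_jitter %||% 0.25
  max_age <- scenario$max_age %||% 120

  bands <- do.call(rbind, lapply(scenario$age_bands, unlist))
  band <- sample.int(nrow(bands), n, replace = TRUE, prob = bands[, 3])
  age0 <- runif(n, bands[band, 1], bands[band, 2])

  lg <- scenario$init_logit
  p1 <- plogis(lg$intercept + lg$slope * (age0 - (scenario$age_origin %||% 50)))
  state0 <- ifelse(runif(n) < p1, 1L, 2L)

  covs <- gm$covariates
  prev <- vapply(covs, function(nm) scenario$covariates[[nm]]$prevalence, 0)
  onset <- vapply(covs, function(nm) scenario$covariates[[nm]]$onset %||% 0, 0)
  recov <- vapply(covs, function(nm)
    scenario$covariates[[nm]]$recovery %||% 0, 0)

  # wave ages: first interview at the baseline age, later waves jittered
  wave_ages <- matrix(age0, n, W)
  if (W > 1)
    for (w in 2:W)
      wave_ages[, w] <- age0 + (w - 1) * iv + runif(n, -jit, jit)

  # covariate paths: baseline Bernoulli(prevalence), then onset/recovery
  # flips at each subsequent wave
  cov_arr <- array(0, dim = c(n, W, length(covs)),
                   dimnames = list(NULL, NULL, covs))
  for (j in seq_along(covs)) {
    cov_arr[, 1, j] <- rbinom(n, 1, prev[j])
    if (W > 1)
      for (w in 2:W) {
        prev_val <- cov_arr[, w - 1, j]
        flip_on <- rbinom(n, 1, onset[j])
        flip_off <- rbinom(n, 1, recov[j])
        cov_arr[, w, j] <- ifelse(prev_val == 1, 1 - flip_off, flip_on)
      }
  }

  # auxiliary response-propensity proxies, correlated with the listed parent
  aux_defs <- scenario$aux %||% list()
  aux_arr <- matrix(0, n, length(aux_defs),
                    dimnames = list(NULL, names(aux_defs)))
  for (a in seq_along(aux_defs)) {
    def <- aux_defs[[a]]
    parent <- cov_arr[, 1, def$parent]
    aux_arr[, a] <- rbinom(n, 1, ifelse(parent == 1, def$p_given_parent,
                                        def$p_given_other))
  }

  lay <- cpp_layout(spec)
  eff <- spec$covariates
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    s_state <- state0[i]
    death_age <- NA_real_
    wstates <- rep(NA_integer_, W)
    wstates[1] <- s_state
    for (w in seq_len(W - 1)) {
      prof <- setNames(as.list(cov_arr[i, w, eff]), eff)
      eta <- eta_profile(spec, gm$params, prof)
      s0 <- match(s_state, lay$alive) - 1L
      jumps <- cpp_sim_segment(s0, wave_ages[i, w], wave_ages[i, w + 1], eta,
                               as.numeric(gm$params$beta_age), lay$tfrom,
                               lay$tto, lay$n_alive, spec$age_origin, 1 / 12)
      if (nrow(jumps)) {
        last <- jumps[nrow(jumps), "state"]
        if (last == lay$n_alive) {
          death_age <- jumps[nrow(jumps), "age"]
          break
        }
        s_state <- lay$alive[last + 1L]
      }
      wstates[w + 1] <- s_state
    }
    nw <- sum(!is.na(wstates))
    df <- data.frame(id = sprintf("s%06d", i),
                     age = wave_ages[i, seq_len(nw)],
                     state = wstates[seq_len(nw)],
                     exact_death = FALSE)
    for (j in seq_along(covs))
      df[[covs[j]]] <- cov_arr[i, seq_len(nw), j]
    for (a in seq_along(aux_defs)) df[[names(aux_defs)[a]]] <- aux_arr[i, a]
    if (!is.na(death_age)) {
      drow <- df[1, , drop = FALSE]
      drow$age <- death_age
      drow$state <- sp$death
      drow$exact_death <- TRUE
      drow[covs] <- NA
      df <- rbind(df, drow)
    }
    rec_list[[i]] <- df
  }
  long <- do.call(rbind, rec_list)
  rownames(long) <- NULL
  panel <- cohort_panel(long, sp, covariates = covs)
  attr(panel, "truth") <- list(scenario = scenario, spec = spec,
                               params = gm$params)
  if (!is.null(scenario$missingness) &&
      !identical(scenario$missingness$mechanism %||% "none", "none")) {
    ms <- scenario$missingness
    panel <- inject_missingness(panel, mechanism = ms$mechanism,
                                rate = ms$rate %||% 0.3,
                                vars = ms$vars %||% covs,
                                seed = seed + 1L)
  }
  panel
}

#' Inject missingness into interview cells
#'
#' Sets state/covariate cells at interviews to `NA` under an MCAR or MAR
#' mechanism; death records are never affected.  The MAR mechanism makes
#' missingness depend only on observed cells: an auxiliary response
#' indicator and the subject's observed status at the following observation
#' (next interview state, or death before it), with an interaction — a
#' mechanism under which complete-case analysis is biased but imputation
#' using all waves is not.  The intercept is calibrated so the realised
#' missingness matches `rate`.
#'
#' @param panel a [cohort_panel()].
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate target overall missingness proportion in the affected cells
#'   (in `[0, 1)`).
#' @param vars variables to affect (default: the panel's covariates).
#' @param aux_var auxiliary column driving the MAR mechanism (default: the
#'   first column named `aux*` in the panel).
#' @param gamma MAR log-odds effects: `c(aux, outcome, interaction)`.
#' @param seed integer RNG seed (required).
#' @return The panel with `NA`s injected; attribute `"miss_mask"` marks the
#'   masked cells and `"masked_values"` stores the removed truth for
#'   recovery scoring.
#' @export
inject_missingness <- function(panel, mechanism = c("MCAR", "MAR"),
                               rate = 0.3, vars = panel$covariates,
                               aux_var = NULL,
                               gamma = c(aux = 1.0, outcome = 1.0,
                                         interaction = 1.5),
                               seed) {
  mechanism <- match.arg(mechanism)
  if (missing(seed)) stop("'seed' is required")
  if (rate >= 1 || rate < 0) stop("rate must be in [0, 1)")
  if (rate == 0) return(panel)
  set.seed(seed)
  d <- panel$data
  sp <- panel$state_space
  interview <- is.na(d$state) | d$state != sp$death
  idx <- which(interview)
  if (mechanism == "MCAR") {
    prob <- rep(rate, length(idx))
  } else {
    if (is.null(aux_var)) {
      aux_candidates <- grep("^aux", names(d), value = TRUE)
      if (!length(aux_candidates))
        stop("MAR mechanism needs an auxiliary column (aux*)")
      aux_var <- aux_candidates[1]
    }
    aux <- as.numeric(d[[aux_var]][idx])
    # observed status at the subject's next observation: transition into the
    # not-healthy-and/or-not-working state or death
    nxt <- c(d$state[-1], NA)
    same <- c(d$id[-1] == d$id[-nrow(d)], FALSE)
    outcome <- as.numeric(!is.na(nxt) & nxt >= 2)[idx]
    outcome[!same[idx]] <- 0
    lp0 <- gamma[1] * aux + gamma[2] * outcome + gamma[3] * aux * outcome
    alpha <- uniroot(function(a) mean(plogis(a + lp0)) - rate,
                     c(-30, 30))$root
    prob <- plogis(alpha + lp0)
  }
  mask_rows <- list()
  masked <- list()
  for (v in vars) {
    hit <- idx[runif(length(idx)) < prob]
    hit <- hit[!is.na(d[[v]][hit])]
    masked[[v]] <- data.frame(row = hit, value = d[[v]][hit])
    d[[v]][hit] <- NA
    mask_rows[[v]] <- hit
  }
  panel$data <- d
  attr(panel, "miss_mask") <- mask_rows
  attr(panel, "masked_values") <- masked
  panel
}
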