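test_that("the generator evaluates the log-linear intensity model", {
  sp <- msm_spec(two_state_space())
  pr <- msm_params(sp, logq0 = -2, beta_age = log(1.07))
  Q50 <- build_generator(sp, pr, 50)
  expect_equal(Q50[1, 2], exp(-2), tolerance = 1e-10)
  expect_equal(Q50[1, 1], -exp(-2), tolerance = 1e-10)
  Q60 <- build_generator(sp, pr, 60)
  expect_equal(Q60[1, 2], exp(-2) * 1.07^10, tolerance = 1e-10)
})

test_that("generator rows sum to zero and respect the transition mask", {
  set.seed(11)
  for (preset in c(3, 5)) {
    sp <- msm_spec(hwle_states(preset))
    K <- nrow(sp$transitions)
    pr <- msm_params(sp, logq0 = runif(K, -4, -1),
                     beta_age = runif(K, -0.1, 0.1))
    Q <- build_generator(sp, pr, runif(1, 50, 90))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    off <- Q[!diag(nrow(Q)) & !sp$state_space$allowed]
    expect_true(all(off == 0))              # disallowed entries exactly 0
    expect_true(all(Q[!diag(nrow(Q))] >= 0))
  }
})

test_that("a fully constrained covariate leaves the generator unchanged", {
  sp <- msm_spec(hwle_states(3), covariates = "z",
                 constraints = fix_hrr("z", c(1, 1, 2, 2), c(2, 3, 1, 3)))
  pr <- msm_params(sp, logq0 = c(-2, -5, -1, -4), beta_age = 0.05,
                   beta = matrix(0, 4, 1))
  Q0 <- build_generator(sp, pr, 60, covariates = c(z = 0))
  Q1 <- build_generator(sp, pr, 60, covariates = c(z = 1))
  expect_identical(Q0, Q1)
})

test_that("missing covariate values point the caller to imputation", {
  sp <- msm_spec(hwle_states(3), covariates = "oa")
  pr <- msm_params(sp, logq0 = -2, beta_age = 0, beta = matrix(0.3, 4, 1))
  expect_error(build_generator(sp, pr, 55, covariates = c(oa = NA)),
               "pmm_impute")
})

test_that("interval probabilities match the exponential closed form", {
  sp <- msm_spec(two_state_space())
  pr <- msm_params(sp, logq0 = log(0.1), beta_age = 0)
  P <- interval_probability(sp, pr, 50, 51)
  expect_equal(P[1, 2], 1 - exp(-0.1), tolerance = 1e-10)
  expect_identical(interval_probability(sp, pr, 60, 60),
                   diag(2) |> `dimnames<-`(list(c("alive", "dead"),
                                                c("alive", "dead"))))
})

test_that("interval probability matrices are stochastic", {
  set.seed(12)
  for (preset in c(3, 5)) {
    sp <- msm_spec(hwle_states(preset))
    K <- nrow(sp$transitions)
    for (r in 1:5) {
      pr <- msm_params(sp, logq0 = runif(K, -4, -1),
                       beta_age = runif(K, -0.05, 0.1))
      a0 <- runif(1, 50, 80)
      P <- interval_probability(sp, pr, a0, a0 + runif(1, 0.1, 6))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
      expect_true(all(P >= 0 & P <= 1 + 1e-12))
    }
  }
})

test_that("piecewise chaining agrees with a Kolmogorov-forward ODE solve", {
  # spot check; the full randomized comparison runs in the acceptance suite
  library(deSolve)
  set.seed(13)
  sp <- msm_spec(hwle_states(3), step = 0.02)
  for (r in 1:10) {
    pr <- msm_params(sp, logq0 = runif(4, -4, -1),
                     beta_age = runif(4, -0.05, 0.1))
    a0 <- runif(1, 50, 85); a1 <- a0 + runif(1, 0.5, 5)
    P <- interval_probability(sp, pr, a0, a1)
    rhs <- function(t, y, parms)
      list(as.vector(matrix(y, 3, 3) %*% build_generator(sp, pr, t)))
    sol <- deSolve::ode(y = as.vector(diag(3)), times = c(a0, a1),
                        func = rhs, rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(P - matrix(sol[2, -1], 3, 3))), 1e-6)
  }
})

test_that("the exact-death likelihood matches its closed form", {
  sp <- msm_spec(two_state_space())
  pr <- msm_params(sp, logq0 = log(0.1), beta_age = 0)
  h <- data.frame(id = "a", age = c(50, 52), state = c(1, 2),
                  exact_death = c(FALSE, TRUE))
  expect_equal(subject_loglik(sp, pr, h), -0.2 + log(0.1),
               tolerance = 1e-9)
})

test_that("zero exit intensities give probability-one contributions", {
  sp <- msm_spec(hwle_states(3))
  pr <- msm_params(sp, logq0 = rep(-40, 4), beta_age = 0)
  h <- data.frame(id = "a", age = c(50, 55), state = c(1, 1),
                  exact_death = FALSE)
  expect_equal(subject_loglik(sp, pr, h), 0, tolerance = 1e-12)
})

test_that("paths impossible under the mask yield -Inf, not an error", {
  allowed <- matrix(FALSE, 3, 3)
  allowed[1, 2] <- allowed[1, 3] <- allowed[2, 3] <- TRUE  # no 2 -> 1 return
  sp <- msm_spec(state_space(c("HW", "nHW"), allowed))
  pr <- msm_params(sp, logq0 = c(-2, -4, -4), beta_age = 0)
  h <- data.frame(id = "a", age = c(50, 52), state = c(2, 1),
                  exact_death = FALSE)
  expect_identical(subject_loglik(sp, pr, h), -Inf)
})

test_that("the constant-hazard MLE equals deaths over person-time", {
  dat <- two_state_panel(n = 1500, lam = 0.1, cens = 8, seed = 2)
  spc <- msm_spec(two_state_space(), fix_age = TRUE)
  fit <- fit_msm(spc, dat$panel)
  closed <- dat$deaths / dat$person_time
  expect_true(fit$converged)
  expect_lt(abs(exp(fit$theta[1]) - closed) / closed, 1e-6)
  expect_lt(abs(exp(fit$theta[1]) - 0.1), 3 * 0.1 / sqrt(dat$deaths))
})

test_that("the likelihood at the optimum is at least the likelihood at truth", {
  sc <- small_scenario(n = 300, waves = 3)
  panel <- simulate_cohort(sc, seed = 21)
  spec <- msm_spec(hwle_states(3))
  gm <- hwle:::scenario_model(sc)
  truth <- msm_params(spec, gm$params$logq0, gm$params$beta_age)
  fit <- suppressWarnings(fit_msm(spec, panel, init = truth))
  ivd <- hwle:::build_interval_data(spec, panel, "omit")
  ll_truth <- sum(hwle:::interval_loglik_vec(spec, truth, ivd))
  expect_gte(fit$loglik, ll_truth)
})

test_that("constraining a covariate everywhere reproduces the age-only fit", {
  sc <- small_scenario(n = 300, waves = 3)
  panel <- simulate_cohort(sc, seed = 22)
  spec0 <- msm_spec(hwle_states(3))
  specc <- msm_spec(hwle_states(3), covariates = "oa",
                    constraints = fix_hrr("oa", c(1, 1, 2, 2),
                                          c(2, 3, 1, 3)))
  f0 <- suppressWarnings(fit_msm(spec0, panel))
  fc <- suppressWarnings(fit_msm(specc, panel))
  expect_equal(fc$loglik, f0$loglik, tolerance = 1e-8)
  expect_equal(unname(fc$theta), unname(f0$theta), tolerance = 1e-5)
})

test_that("rare transitions trigger an informative warning", {
  d <- data.frame(id = rep(1:30, each = 2),
                  age = as.vector(rbind(55, 57)),
                  state = as.vector(rbind(1L, rep(c(1L, 2L), 15))),
                  exact_death = FALSE)
  panel <- cohort_panel(d, hwle_states(3))
  w <- capture_warnings(fit_msm(msm_spec(hwle_states(3)), panel))
  expect_true(any(grepl("HW-dead", w)))
})

test_that("the hazard-ratio table formats estimates and constraints", {
  sp <- msm_spec(hwle_states(3), covariates = "noauto",
                 constraints = fix_hrr("noauto", 2, c(1, 3)))
  # synthetic fit object with known coefficients
  theta <- c(rep(-2, 4), rep(0.05, 4), 0, 0)
  names(theta) <- hwle:::param_names(sp)
  fit <- structure(list(spec = sp, theta = theta,
                        cov = diag(0.1^2, 10), converged = TRUE),
                   class = "hwle_fit")
  tab <- hazard_ratio_table(fit)
  row <- tab[tab$transition == "HW-nHW" & tab$effect == "noauto", ]
  expect_equal(row$hrr, 1, tolerance = 1e-12)
  expect_equal(round(row$lcl, 2), 0.82)
  expect_equal(round(row$ucl, 2), 1.22)
  expect_equal(tab$formatted[tab$transition == "nHW-HW" &
                               tab$effect == "noauto"], "1.00 (fixed)")
  expect_equal(tab$transition[tab$effect == "age"],
               c("HW-nHW", "HW-dead", "nHW-HW", "nHW-dead"))
})
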