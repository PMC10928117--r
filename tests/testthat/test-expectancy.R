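fit_like <- function(spec, params) list(spec = spec, params = params)

test_that("zero intensities leave the occupancy at its starting indicator", {
  sp <- msm_spec(hwle_states(3))
  pr <- msm_params(sp, logq0 = rep(-60, 4), beta_age = 0)
  oc <- occupancy_curve(fit_like(sp, pr), start_age = 50, max_age = 70,
                        h = 0.5)
  expect_true(all(abs(oc$occ[, 1, 1] - 1) < 1e-12))
  expect_true(all(abs(oc$occ[, 2, 2] - 1) < 1e-12))
  expect_equal(unname(state_expectancy(oc, 1)), c(20, 0), tolerance = 1e-9)
})

test_that("constant-hazard occupancy and life expectancy match closed forms", {
  sp <- msm_spec(two_state_space())
  pr <- msm_params(sp, logq0 = log(0.1), beta_age = 0)
  oc <- occupancy_curve(fit_like(sp, pr), start_age = 50, max_age = 120,
                        h = 0.05)
  i60 <- which.min(abs(oc$ages - 60))
  expect_equal(oc$occ[i60, 1, 1], exp(-1), tolerance = 1e-9)
  le <- state_expectancy(oc, 1)
  expect_lt(abs(le - (1 - exp(-7)) / 0.1), 1e-3)
})

test_that("occupancy rows sum to one and death occupancy is non-decreasing", {
  set.seed(31)
  sp <- msm_spec(hwle_states(3))
  pr <- msm_params(sp, logq0 = runif(4, -4, -1),
                   beta_age = runif(4, -0.05, 0.1))
  oc <- occupancy_curve(fit_like(sp, pr), h = 0.25)
  for (s in 1:2) {
    expect_lt(max(abs(rowSums(oc$occ[, , s]) - 1)), 1e-8)
    expect_true(all(diff(oc$occ[, 3, s]) >= -1e-12))
  }
  expect_equal(oc$occ[1, , 1], c(HW = 1, nHW = 0, dead = 0))
})

test_that("expectancies decompose exactly into total life expectancy", {
  set.seed(32)
  sp <- msm_spec(hwle_states(3))
  for (r in 1:5) {
    pr <- msm_params(sp, logq0 = runif(4, -4, -1),
                     beta_age = runif(4, -0.05, 0.1))
    w <- runif(1, 0.05, 0.95)
    e <- marginal_expectancies(fit_like(sp, pr), c(w, 1 - w))
    expect_lt(abs(sum(e$marginal) - e$le), 1e-8)
    expect_true(all(e$marginal >= 0))
    expect_true(all(e$marginal <= 70))
    # marginal lies between the conditional extremes
    for (s in 1:2)
      expect_true(e$marginal[s] >= min(e$conditional[, s]) - 1e-10 &&
                    e$marginal[s] <= max(e$conditional[, s]) + 1e-10)
  }
})

test_that("raising mortality strictly lowers life expectancy", {
  sp <- msm_spec(hwle_states(3))
  pr <- msm_params(sp, logq0 = c(-2, -5, -1, -4.5), beta_age = 0.05)
  le1 <- marginal_expectancies(fit_like(sp, pr), c(0.3, 0.7))$le
  pr2 <- pr
  pr2$logq0[c("HW-dead", "nHW-dead")] <-
    pr$logq0[c("HW-dead", "nHW-dead")] + log(1.5)
  le2 <- marginal_expectancies(fit_like(sp, pr2), c(0.3, 0.7))$le
  expect_lt(le2, le1)
})

test_that("halving the grid step changes expectancies by less than 0.005 years", {
  sp <- msm_spec(hwle_states(3))
  pr <- msm_params(sp, logq0 = c(-2.3, -6.9, -0.8, -5.7),
                   beta_age = c(0.068, 0.058, -0.15, 0.095))
  e1 <- marginal_expectancies(fit_like(sp, pr), c(0.45, 0.55), h = 0.25)
  e2 <- marginal_expectancies(fit_like(sp, pr), c(0.45, 0.55), h = 0.125)
  expect_lt(max(abs(e1$marginal - e2$marginal)), 0.005)
  expect_lt(abs(e1$le - e2$le), 0.005)
})

test_that("without recovery or mortality from HW, HWLE is the waiting time to exit", {
  # 1 -> 2 only at constant rate: sojourn in HW ~ exponential(q12),
  # truncated at max_age
  allowed <- matrix(FALSE, 3, 3)
  allowed[1, 2] <- allowed[2, 3] <- TRUE
  sp <- msm_spec(state_space(c("HW", "nHW"), allowed))
  q12 <- 0.2
  pr <- msm_params(sp, logq0 = log(c(q12, 0.05)), beta_age = 0)
  oc <- occupancy_curve(fit_like(sp, pr), start_age = 50, max_age = 120,
                        h = 0.05)
  hw_years <- state_expectancy(oc, 1)["HW"]
  expect_equal(unname(hw_years), (1 - exp(-q12 * 70)) / q12,
               tolerance = 1e-3)
})

test_that("the initial-state regression recovers a known logistic law", {
  set.seed(33)
  n <- 8000
  age <- runif(n, 50, 90)
  p1 <- plogis(-0.2 - 0.05 * (age - 50))
  st <- ifelse(runif(n) < p1, 1L, 2L)
  d <- data.frame(id = rep(seq_len(n), each = 2),
                  age = as.vector(rbind(age, age + 2)),
                  state = as.vector(rbind(st, st)), exact_death = FALSE)
  panel <- cohort_panel(d, hwle_states(3))
  id <- initial_state_distribution(panel, at_age = 50)
  expect_equal(unname(id$probs["HW"]), plogis(-0.2), tolerance = 0.03)
  expect_equal(sum(id$probs), 1)
  cf <- coef(id$models[[1]])
  expect_equal(unname(cf[1]), -0.2, tolerance = 3 * 0.08)
  expect_equal(unname(cf[2]), -0.05, tolerance = 3 * 0.004)
})

test_that("a single observed baseline state yields a degenerate distribution", {
  d <- data.frame(id = rep(1:20, each = 2),
                  age = as.vector(rbind(55, 57)),
                  state = 1L, exact_death = FALSE)
  panel <- cohort_panel(d, hwle_states(3))
  expect_warning(id <- initial_state_distribution(panel), "degenerate")
  expect_equal(unname(id$probs), c(1, 0))
})

test_that("degenerate weights reduce the marginal to the conditional", {
  sp <- msm_spec(hwle_states(3))
  pr <- msm_params(sp, logq0 = c(-2, -5, -1, -4), beta_age = 0.05)
  e <- marginal_expectancies(fit_like(sp, pr), c(1, 0))
  expect_equal(unname(e$marginal), unname(e$conditional["HW", ]),
               tolerance = 1e-12)
})

test_that("zero covariance collapses the simulation interval to the point", {
  dat <- two_state_panel(n = 400, lam = 0.08, cens = 10, seed = 34)
  fit <- fit_msm(msm_spec(two_state_space(), fix_age = TRUE), dat$panel)
  fit$cov <- matrix(0, 1, 1)
  est <- expectancy_uncertainty(fit, c(1), n_draws = 50, seed = 9)
  expect_equal(est$table$low, est$table$point, tolerance = 1e-10)
  expect_equal(est$table$high, est$table$point, tolerance = 1e-10)
})

test_that("identical seeds give identical intervals", {
  dat <- two_state_panel(n = 400, lam = 0.08, cens = 10, seed = 35)
  fit <- fit_msm(msm_spec(two_state_space(), fix_age = TRUE), dat$panel)
  e1 <- expectancy_uncertainty(fit, c(1), n_draws = 100, seed = 77)
  e2 <- expectancy_uncertainty(fit, c(1), n_draws = 100, seed = 77)
  expect_identical(e1$table, e2$table)
})

test_that("simulation intervals cover the true life expectancy at near-nominal rates", {
  # 100 small cohorts from a known constant-hazard model; the 95% interval
  # for truncated LE should cover the truth 90-99% of the time
  lam <- 0.08
  le_true <- (1 - exp(-lam * 65)) / lam   # from age 55 to 120
  hits <- logical(100)
  spc <- msm_spec(two_state_space(), fix_age = TRUE)
  for (r in seq_len(100)) {
    dat <- two_state_panel(n = 250, lam = lam, cens = 12, seed = 4000 + r)
    fit <- fit_msm(spc, dat$panel)
    est <- expectancy_uncertainty(fit, c(1), n_draws = 300, seed = r,
                                  start_age = 55, h = 0.25)
    hits[r] <- est$table$low[2] <= le_true && le_true <= est$table$high[2]
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("the 5-state variant decomposes and weights like the 3-state one", {
  set.seed(37)
  sp <- msm_spec(hwle_states(5))
  K <- nrow(sp$transitions)
  pr <- msm_params(sp, logq0 = runif(K, -4.5, -1.5),
                   beta_age = runif(K, -0.05, 0.1))
  w <- c(0.27, 0.37, 0.05, 0.31)
  e <- marginal_expectancies(fit_like(sp, pr), w)
  expect_lt(abs(sum(e$marginal) - e$le), 1e-8)
  oc <- occupancy_curve(fit_like(sp, pr), h = 0.5)
  for (s in 1:4) expect_lt(max(abs(rowSums(oc$occ[, , s]) - 1)), 1e-8)
})

test_that("the 5-state initial-state regression returns normalised probabilities", {
  set.seed(38)
  n <- 3000
  age <- runif(n, 50, 85)
  st <- sample(1:4, n, replace = TRUE, prob = c(0.27, 0.37, 0.05, 0.31))
  d <- data.frame(id = rep(seq_len(n), each = 2),
                  age = as.vector(rbind(age, age + 2)),
                  state = as.vector(rbind(st, st)), exact_death = FALSE)
  panel <- cohort_panel(d, hwle_states(5))
  id <- initial_state_distribution(panel, at_age = 50)
  expect_equal(sum(id$probs), 1, tolerance = 1e-10)
  expect_equal(unname(id$probs),
               c(0.27, 0.37, 0.05, 0.31), tolerance = 0.05)
})

test_that("the expectancy table lays out profiles with interval columns", {
  sc <- small_scenario(n = 500, waves = 4)
  panel <- simulate_cohort(sc, seed = 36)
  spec <- scenario_spec()
  fit <- suppressWarnings(fit_msm(spec, panel))
  init <- initial_state_distribution(panel)
  tab <- expectancy_table(fit, init, data.frame(pain = c(0, 1)),
                          n_draws = 100, seed = 5)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("pain", "HW_point", "HW_low", "HW_high", "LE_point")
                  %in% names(tab)))
  expect_lt(tab$HW_point[2], tab$HW_point[1])  # pain lowers HWLE
  expect_lt(max(abs(tab$HW_point + tab$nHW_point - tab$LE_point)), 1e-8)
})
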