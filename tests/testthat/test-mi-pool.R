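test_that("Rubin's rules reproduce the hand-worked example", {
  pl <- rubin_pool(c(1.0, 1.2, 0.8), rep(0.04, 3))
  expect_equal(pl$point, 1.0, tolerance = 1e-12)
  expect_equal(pl$between_var, 0.04, tolerance = 1e-12)
  expect_equal(pl$within_var, 0.04, tolerance = 1e-12)
  expect_equal(pl$total_var, 0.04 + (4 / 3) * 0.04, tolerance = 1e-10)
  expect_equal(pl$total_var,
               pl$within_var + (1 + 1 / pl$m_used) * pl$between_var)
})

test_that("identical points collapse to the single-imputation Wald interval", {
  pl <- rubin_pool(rep(0.5, 10), rep(0.04, 10))
  expect_equal(pl$between_var, 0)
  expect_equal(pl$total_var, 0.04)
  # df -> large, so the t quantile approaches the normal one
  expect_equal(pl$ci95, 0.5 + c(-1, 1) * qnorm(0.975) * 0.2,
               tolerance = 1e-3)
})

test_that("pooling is permutation-invariant and total >= within always", {
  set.seed(41)
  for (r in 1:20) {
    pts <- rnorm(7)
    vrs <- rexp(7, 10)
    p1 <- rubin_pool(pts, vrs)
    idx <- sample(7)
    p2 <- rubin_pool(pts[idx], vrs[idx])
    expect_equal(p1$point, p2$point)
    expect_equal(p1$total_var, p2$total_var)
    expect_gte(p1$total_var, p1$within_var)
  }
})

test_that("pooling log-HRRs then exponentiating gives the geometric mean", {
  hrrs <- c(1.3, 1.6, 1.1, 1.45)
  pl <- rubin_pool(log(hrrs), rep(0.01, 4))
  expect_equal(exp(pl$point), prod(hrrs)^(1 / 4), tolerance = 1e-12)
})

test_that("Barnard-Rubin df shrinks below the classical value for finite dfcom", {
  m <- 5; b <- 0.02; tv <- 0.1
  lambda <- (1 + 1 / m) * b / tv
  dfold <- (m - 1) / lambda^2
  expect_equal(barnard_rubin(m, b, tv), dfold)
  expect_lt(barnard_rubin(m, b, tv, dfcom = 100), dfold)
  expect_gt(barnard_rubin(m, b, tv, dfcom = 100), 0)
})

test_that("pooling requires at least two imputations", {
  expect_error(rubin_pool(1, 0.1), "at least two")
  expect_error(rubin_pool(c(1, 2), 0.1), "equal length")
})

test_that("a panel without missing cells yields identical copies", {
  sc <- small_scenario(n = 120, waves = 3)
  panel <- simulate_cohort(sc, seed = 42)
  imps <- pmm_impute(panel, M = 4, seed = 43)
  expect_equal(imps$M, 4)
  for (m in 2:4)
    expect_identical(imps$panels[[m]]$data, imps$panels[[1]]$data)
  expect_identical(imps$panels[[1]]$data, panel$data)
})

test_that("imputed binary covariates only take observed donor values", {
  sc <- small_scenario(n = 300, waves = 3)
  panel <- simulate_cohort(sc, seed = 44)
  pm <- inject_missingness(panel, "MCAR", rate = 0.25, vars = "pain",
                           seed = 45)
  imps <- pmm_impute(pm, aux_vars = "aux_resp", M = 2, cycles = 3,
                     seed = 46)
  for (m in 1:2) {
    v <- imps$panels[[m]]$data$pain
    expect_true(all(v[!is.na(v)] %in% c(0, 1)))
    # death records keep their structurally-missing covariates
    dead <- imps$panels[[m]]$data$state == 3
    expect_true(all(is.na(imps$panels[[m]]$data$pain[dead])))
  }
  # only originally-missing cells differ across imputations
  obs <- !is.na(pm$data$pain)
  expect_identical(imps$panels[[1]]$data$pain[obs],
                   imps$panels[[2]]$data$pain[obs])
})

test_that("imputation is deterministic given the seed", {
  sc <- small_scenario(n = 200, waves = 3)
  panel <- simulate_cohort(sc, seed = 47)
  pm <- inject_missingness(panel, "MCAR", rate = 0.2, vars = "pain",
                           seed = 48)
  i1 <- pmm_impute(pm, M = 2, cycles = 3, seed = 49)
  i2 <- pmm_impute(pm, M = 2, cycles = 3, seed = 49)
  expect_identical(i1$panels[[1]]$data, i2$panels[[1]]$data)
  expect_identical(i1$panels[[2]]$data, i2$panels[[2]]$data)
})

test_that("a variable with no complete cases is a named error", {
  d <- data.frame(id = rep(1:20, each = 2),
                  age = as.vector(rbind(55, 57)),
                  state = rep(c(1L, 2L), 20),
                  exact_death = FALSE, oa = NA_real_)
  panel <- cohort_panel(d, hwle_states(3), covariates = "oa")
  expect_error(pmm_impute(panel, M = 2, seed = 50), "oa")
})

test_that("MCAR imputation preserves the covariate prevalence", {
  sc <- small_scenario(n = 1200, waves = 4)
  panel <- simulate_cohort(sc, seed = 51)
  alive <- panel$data$state != 3
  prev_complete <- mean(panel$data$pain[alive], na.rm = TRUE)
  pm <- inject_missingness(panel, "MCAR", rate = 0.3, vars = "pain",
                           seed = 52)
  imps <- pmm_impute(pm, aux_vars = "aux_resp", M = 5, cycles = 4,
                     seed = 53)
  prev_imp <- mean(vapply(imps$panels, function(p)
    mean(p$data$pain[alive]), 0))
  expect_lt(abs(prev_imp - prev_complete), 0.03)
})

test_that("non-converged imputation fits are excluded from pooling", {
  sc <- small_scenario(n = 250, waves = 3)
  panel <- simulate_cohort(sc, seed = 54)
  imps <- pmm_impute(panel, M = 4, seed = 55)
  runs <- suppressWarnings(run_per_imputation(imps, msm_spec(hwle_states(3))))
  # mimic one failed convergence among the M fits
  runs$converged[2] <- FALSE
  pooled <- pool_fits(runs)
  expect_true(all(pooled$m_used == 3))
  expect_equal(nrow(pooled), length(runs$fits[[1]]$theta))
})

test_that("with zero missingness pooled estimates equal the complete-data fit", {
  sc <- small_scenario(n = 250, waves = 3)
  panel <- simulate_cohort(sc, seed = 56)
  spec <- msm_spec(hwle_states(3))
  imps <- pmm_impute(panel, M = 3, seed = 57)
  runs <- suppressWarnings(run_per_imputation(imps, spec))
  pooled <- pool_fits(runs)
  fit <- suppressWarnings(fit_msm(spec, panel))
  expect_equal(pooled$hrr, unname(exp(fit$theta)), tolerance = 1e-8)
})
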