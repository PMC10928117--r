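# State-occupancy integration: from fitted transition intensities to
# healthy working life expectancy and total life expectancy from age 50.

#' State-occupancy probabilities over an age grid
#'
#' Propagates the state-occupancy distribution from `start_age` to `max_age`
#' by chaining interval transition probabilities over consecutive grid cells,
#' once for each alive starting state.  Covariates are held fixed over age
#' (time-independence of the covariate profile in the expectancy stage, even
#' for covariates observed time-varying during fitting).
#'
#' @param fit an `hwle_fit`, or any list with elements `spec` and `params`.
#' @param covariates named covariate profile (complete; default all zero).
#' @param start_age,max_age age range in years (`max_age` defaults to the
#'   hard truncation at 120; occupancy mass remaining there contributes no
#'   further years).
#' @param h grid step in years.
#' @return Object of class `occupancy_grid`: `ages`, and `occ`, an array of
#'   dimension (grid age, state, starting alive state) whose rows sum to one.
#' @export
occupancy_curve <- function(fit, covariates = NULL, start_age = 50,
                            max_age = 120, h = 0.25) {
  spec <- fit$spec
  stopifnot(h > 0)
  if (max_age <= start_age) stop("max_age must exceed start_age")
  ages <- seq(start_age, max_age, by = h)
  if (ages[length(ages)] < max_age) ages <- c(ages, max_age)
  eta <- eta_profile(spec, fit$params, covariates)
  lay <- cpp_layout(spec)
  occ_alive <- cpp_occupancy(eta, as.numeric(fit$params$beta_age), lay$tfrom,
                             lay$tto, lay$n_alive, ages, spec$age_origin,
                             min(spec$step, h))
  S <- spec$state_space$n_states
  occ <- array(0, dim = c(length(ages), S, lay$n_alive),
               dimnames = list(NULL, spec$state_space$labels,
                               spec$state_space$labels[lay$alive]))
  occ[, lay$alive, ] <- occ_alive
  for (s in seq_len(lay$n_alive))
    occ[, spec$state_space$death, s] <-
      pmax(0, 1 - rowSums(occ_alive[, , s, drop = FALSE], dims = 1))
  structure(list(ages = ages, occ = occ, state_space = spec$state_space),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("occupancy_grid:", length(x$ages), "grid ages from", x$ages[1], "to",
      x$ages[length(x$ages)], "\n")
  invisible(x)
}

trapz_weights <- function(ages) {
  n <- length(ages)
  w <- numeric(n)
  d <- diff(ages)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Expected years spent in a state
#'
#' Trapezoidal integration of a state's occupancy probability over the age
#' grid.  Evaluated for the healthy-and-working state this is the healthy
#' working life expectancy (HWLE) from the grid's starting age.
#'
#' @param grid an [occupancy_curve()] result.
#' @param state state index or label.
#' @return named numeric vector of expected years, one entry per alive
#'   starting state.
#' @export
state_expectancy <- function(grid, state) {
  if (is.character(state))
    state <- match(state, grid$state_space$labels)
  w <- trapz_weights(grid$ages)
  apply(grid$occ[, state, , drop = FALSE], 3, function(m) sum(w * m))
}

# (start state) x (alive state) matrix of conditional expectancies
conditional_expectancies <- function(grid) {
  sp <- grid$state_space
  alive <- setdiff(seq_len(sp$n_states), sp$death)
  E <- sapply(alive, function(s) state_expectancy(grid, s))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  # sapply rows follow the starting state, columns the occupied state
  dimnames(E) <- list(start = sp$labels[alive], state = sp$labels[alive])
  E
}

#' Initial-state distribution at a given age
#'
#' Models the probability of each alive state at a subject's first interview
#' as a function of baseline age — logistic regression for two alive states,
#' one-vs-rest logistic regressions normalised to sum to one otherwise — and
#' evaluates the fitted law at `at_age`.  This supplies the weights for
#' population-marginal expectancies.
#'
#' @param panel a [cohort_panel()].
#' @param at_age evaluation age (years), default 50.
#' @return Object of class `init_dist`: `probs` (named, sums to one),
#'   `at_age`, and the fitted model(s).
#' @export
initial_state_distribution <- function(panel, at_age = 50) {
  sp <- panel$state_space
  base <- baseline_records(panel)
  base <- base[!is.na(base$state), , drop = FALSE]
  alive <- setdiff(seq_len(sp$n_states), sp$death)
  obs <- table(factor(base$state, levels = alive))
  if (sum(obs > 0) < 2L) {
    warning("fewer than two alive states observed at baseline; ",
            "returning a degenerate initial-state distribution")
    probs <- as.numeric(obs > 0)
    return(structure(list(probs = setNames(probs / sum(probs),
                                           sp$labels[alive]),
                          at_age = at_age, models = NULL),
                     class = "init_dist"))
  }
  agec <- base$age - at_age
  if (length(alive) == 2L) {
    m <- glm(I(base$state == alive[1]) ~ agec, family = binomial())
    p1 <- plogis(coef(m)[1])
    probs <- c(p1, 1 - p1)
    models <- list(m)
  } else {
    models <- lapply(alive, function(s)
      glm(I(base$state == s) ~ agec, family = binomial()))
    raw <- vapply(models, function(m) plogis(coef(m)[1]), 0)
    probs <- raw / sum(raw)
  }
  structure(list(probs = setNames(as.numeric(probs), sp$labels[alive]),
                 at_age = at_age, models = models),
            class = "init_dist")
}

#' @export
print.init_dist <- function(x, ...) {
  cat("Initial-state distribution at age", x$at_age, ":\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Marginal and conditional state expectancies (point estimates)
#'
#' Conditional expectancies (rows: starting state) come from
#' [occupancy_curve()]; marginal expectancies weight them by the
#' initial-state distribution, and total life expectancy is the sum of the
#' marginal alive-state expectancies (the decomposition
#' HWLE + years not healthy and/or not working = LE holds exactly, up to
#' floating point, by construction).
#'
#' @param fit an `hwle_fit`.
#' @param init_dist an [initial_state_distribution()] result, or a numeric
#'   vector of probabilities over alive states.
#' @inheritParams occupancy_curve
#' @return Object of class `expectancy_point`: `conditional` (matrix),
#'   `marginal` (named vector of years per alive state), `le` (total life
#'   expectancy), and the settings used.
#' @export
marginal_expectancies <- function(fit, init_dist, covariates = NULL,
                                  start_age = 50, max_age = 120, h = 0.25) {
  w <- if (inherits(init_dist, "init_dist")) init_dist$probs else init_dist
  w <- as.numeric(w)
  stopifnot(length(w) == fit$spec$state_space$n_alive,
            abs(sum(w) - 1) < 1e-8, all(w >= 0))
  grid <- occupancy_curve(fit, covariates, start_age, max_age, h)
  E <- conditional_expectancies(grid)
  marg <- as.numeric(w %*% E)
  names(marg) <- colnames(E)
  structure(list(conditional = E, marginal = marg, le = sum(marg),
                 weights = w, covariates = covariates,
                 start_age = start_age, max_age = max_age, h = h),
            class = "expectancy_point")
}

#' @export
print.expectancy_point <- function(x, ...) {
  cat("Expected years from age", x$start_age, "by state (marginal):\n")
  print(round(x$marginal, 3))
  cat("Total life expectancy:", round(x$le, 3), "years\n")
  invisible(x)
}

nearest_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (all(e$values >= 0)) return(V)
  warning("covariance not positive semi-definite; ",
          "negative eigenvalues clipped to zero")
  e$vectors %*% diag(pmax(e$values, 0), length(e$values)) %*% t(e$vectors)
}

#' State expectancies with simulation-based confidence intervals
#'
#' Draws parameter vectors from the multivariate normal distribution of the
#' MLE, recomputes marginal expectancies for each draw, and reports 2.5/97.5
#' percentile intervals.  Deterministic given `seed`.
#'
#' @inheritParams marginal_expectancies
#' @param n_draws number of parameter draws (default 1000).
#' @param seed integer RNG seed (required: the intervals are Monte-Carlo).
#' @return Object of class `expectancy_estimate`: data.frame `table` with
#'   one row per alive state plus a total-LE row (`point`, `low`, `high`),
#'   the matrix of per-draw marginal expectancies, `n_draws` and `seed`.
#' @export
expectancy_uncertainty <- function(fit, init_dist, covariates = NULL,
                                   n_draws = 1000, seed,
                                   start_age = 50, max_age = 120, h = 0.25) {
  if (missing(seed)) stop("'seed' is required for reproducible intervals")
  if (is.null(fit$cov)) stop("fit has no covariance (non-converged?)")
  point <- marginal_expectancies(fit, init_dist, covariates, start_age,
                                 max_age, h)
  set.seed(seed)
  V <- nearest_psd(fit$cov)
  draws <- MASS::mvrnorm(n_draws, fit$theta, V)
  if (n_draws == 1) draws <- matrix(draws, 1)
  w <- point$weights
  spec <- fit$spec
  lay <- cpp_layout(spec)
  ages <- seq(start_age, max_age, by = h)
  if (ages[length(ages)] < max_age) ages <- c(ages, max_age)
  wts <- trapz_weights(ages)
  M <- matrix(NA_real_, n_draws, spec$state_space$n_alive + 1L)
  for (i in seq_len(n_draws)) {
    pr <- unpack_params(spec, draws[i, ])
    eta <- eta_profile(spec, pr, covariates)
    occ <- cpp_occupancy(eta, as.numeric(pr$beta_age), lay$tfrom, lay$tto,
                         lay$n_alive, ages, spec$age_origin, min(spec$step, h))
    E <- apply(occ, c(2, 3), function(col) sum(wts * col))  # state x start
    marg <- as.numeric(E %*% w)
    M[i, ] <- c(marg, sum(marg))
  }
  labs <- c(spec$state_space$labels[lay$alive], "LE")
  colnames(M) <- labs
  qs <- apply(M, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tab <- data.frame(state = labs,
                    point = c(point$marginal, point$le),
                    low = qs[1, ], high = qs[2, ], row.names = NULL)
  structure(list(table = tab, draws = M, n_draws = n_draws, seed = seed,
                 point = point),
            class = "expectancy_estimate")
}

#' @export
print.expectancy_estimate <- function(x, digits = 2, ...) {
  cat("Expected years from age", x$point$start_age,
      "(95% simulation intervals,", x$n_draws, "draws):\n")
  tab <- x$table
  tab$formatted <- sprintf("%.*f (%.*f,%.*f)", digits, tab$point,
                           digits, tab$low, digits, tab$high)
  print(tab[c("state", "formatted")], row.names = FALSE)
  invisible(x)
}

#' Expectancy table over covariate profiles
#'
#' Computes, for each row of `profiles`, the marginal expectancies and their
#' simulation intervals — the standard reporting layout: HWLE (95% CI),
#' years not healthy and/or not in work (95% CI), life expectancy (95% CI),
#' one row per covariate profile.
#'
#' @inheritParams expectancy_uncertainty
#' @param profiles data.frame with one column per model covariate; each row
#'   is a profile.  For the age-only model use a 1-row, 0-column data.frame.
#' @return data.frame with the profile columns plus, per alive state and for
#'   LE, `point`/`low`/`high` columns.
#' @export
expectancy_table <- function(fit, init_dist, profiles, n_draws = 1000, seed,
                             start_age = 50, max_age = 120, h = 0.25) {
  if (missing(seed)) stop("'seed' is required")
  out <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    prof <- as.list(profiles[i, , drop = FALSE])
    est <- expectancy_uncertainty(fit, init_dist, prof, n_draws,
                                  seed = seed + i - 1L,
                                  start_age = start_age, max_age = max_age,
                                  h = h)
    wide <- est$table
    row <- cbind(profiles[i, , drop = FALSE],
                 setNames(as.data.frame(as.list(c(
                   rbind(wide$point, wide$low, wide$high)))),
                   paste(rep(wide$state, each = 3),
                         c("point", "low", "high"), sep = "_")))
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
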