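# Interval construction and maximum likelihood estimation for the
# panel-observed multi-state model.

# Turn a validated panel into the flat interval arrays consumed by the C++
# likelihood kernel.  Covariates enter at their value at the interval start.
# na_action:
#   "error"  - any missing state/covariate cell is an error (send the caller
#              to pmm_impute)
#   "omit"   - complete-case: interview rows with a missing state or missing
#              model covariate are dropped, and intervals re-formed from the
#              remaining consecutive records (the bridging interval is valid
#              under the Markov assumption)
build_interval_data <- function(spec, panel,
                                na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  stopifnot(inherits(panel, "cohort_panel"))
  sp <- spec$state_space
  if (!identical(sp$allowed, panel$state_space$allowed))
    stop("panel and spec use different state spaces")
  miss <- setdiff(spec$covariates, panel$covariates)
  if (length(miss))
    stop("covariate(s) not in panel: ", paste(miss, collapse = ", "))
  d <- panel$data
  vars <- c("state", spec$covariates)
  any_na <- Reduce(`|`, lapply(vars, function(v) is.na(d[[v]])))
  is_death <- !is.na(d$state) & d$state == sp$death
  any_na <- any_na & !is_death   # death records carry no interview items
  if (any(any_na)) {
    if (na_action == "error")
      stop("panel contains ", sum(any_na), " interview row(s) with missing ",
           "state or covariate values; impute first (see pmm_impute) or ",
           "refit with na_action = \"omit\"")
    d <- d[!any_na, , drop = FALSE]
  }
  ids <- d$id
  n <- nrow(d)
  first <- !duplicated(ids)
  prev_ok <- c(FALSE, ids[-1] == ids[-n])          # row has a predecessor
  to_row <- which(prev_ok)
  from_row <- to_row - 1L
  # start state must be alive (death is always last within subject)
  keep <- d$state[from_row] != sp$death
  to_row <- to_row[keep]; from_row <- from_row[keep]
  if (!length(to_row)) stop("no usable observation intervals")
  p <- length(spec$covariates)
  X <- matrix(0, length(to_row), p)
  for (j in seq_len(p)) X[, j] <- as.numeric(d[[spec$covariates[j]]][from_row])
  alive <- setdiff(seq_len(sp$n_states), sp$death)
  list(from = match(d$state[from_row], alive) - 1L,
       to = ifelse(d$state[to_row] == sp$death, sp$n_alive,
                   match(d$state[to_row], alive) - 1L),
       exact = d$exact_death[to_row],
       a0 = d$age[from_row], a1 = d$age[to_row],
       X = X,
       subject = ids[to_row],
       n_subjects = length(unique(ids)))
}

interval_loglik_vec <- function(spec, params, ivd) {
  K <- nrow(spec$transitions)
  ETA <- matrix(params$logq0, nrow(ivd$X), K, byrow = TRUE)
  if (length(spec$covariates))
    ETA <- ETA + ivd$X %*% t(params$beta)
  lay <- cpp_layout(spec)
  cpp_interval_loglik(ETA, as.numeric(params$beta_age), lay$tfrom, lay$tto,
                      lay$n_alive, ivd$from, ivd$to, ivd$exact,
                      ivd$a0, ivd$a1, spec$age_origin, spec$step)
}

#' Log-likelihood of one subject's observation history
#'
#' Sums the interval contributions for a single subject: transitions between
#' alive states observed at interview ages contribute `log P_rs(t0, t1)`
#' (covariates fixed at their interval-start values); an exact death age
#' contributes the probability of reaching any alive state by the death age
#' times the intensity of dying from it, summed over alive states (the state
#' immediately before death is unknown).  An impossible path under the
#' permitted-transition mask yields `-Inf`, not an error.
#'
#' @param spec an [msm_spec()].
#' @param params an [msm_params()].
#' @param history data.frame of one subject's records (columns as in
#'   [cohort_panel()]).
#' @return scalar log-likelihood (finite or `-Inf`).
#' @export
subject_loglik <- function(spec, params, history) {
  if (!"exact_death" %in% names(history))
    history$exact_death <- !is.na(history$state) &
      history$state == spec$state_space$death
  if (!"id" %in% names(history)) history$id <- "s1"
  panel <- cohort_panel(history, spec$state_space, spec$covariates)
  ivd <- build_interval_data(spec, panel)
  sum(interval_loglik_vec(spec, params, ivd))
}

# crude initial values: observed transition counts divided by person-time at
# risk in the starting state, treating panel transitions as if observed
# directly (the standard crude-rate initialisation)
crude_inits <- function(spec, ivd) {
  K <- nrow(spec$transitions)
  sp <- spec$state_space
  alive <- setdiff(seq_len(sp$n_states), sp$death)
  lay <- cpp_layout(spec)
  len <- ivd$a1 - ivd$a0
  counts <- numeric(K)
  ptime <- numeric(sp$n_alive)
  for (s in seq_len(sp$n_alive) - 1L)
    ptime[s + 1L] <- sum(len[ivd$from == s])
  for (k in seq_len(K)) {
    counts[k] <- sum(ivd$from == lay$tfrom[k] & ivd$to == lay$tto[k])
    if (lay$tto[k] == sp$n_alive)  # deaths observed either exactly or not
      counts[k] <- sum(ivd$from == lay$tfrom[k] & ivd$to == sp$n_alive)
  }
  rate <- pmax(counts, 0.5) / pmax(ptime[lay$tfrom + 1L], 1e-8)
  log(rate)
}

#' Fit the multi-state model by maximum likelihood
#'
#' Maximises the panel likelihood over the free parameters by quasi-Newton
#' (BFGS) iteration, polishes the optimum with up to two Newton steps using a
#' finite-difference Hessian, and reports the covariance as the inverse of
#' the negative Hessian at the optimum.  Non-convergence is reported through
#' the `converged` flag rather than an error, so that multiply-imputed
#' analyses can drop failed fits when pooling.
#'
#' @param spec an [msm_spec()].
#' @param panel a validated [cohort_panel()].
#' @param init `"crude"` (observed transition counts over person-time), or an
#'   [msm_params()] object of starting values.
#' @param na_action `"error"` (default) or `"omit"` (complete-case); see
#'   Details in [pmm_impute()] for the imputation route.
#' @param control list passed to [stats::optim()] (defaults:
#'   `maxit = 500`, `reltol = 1e-12`).
#' @return Object of class `hwle_fit`: the spec, MLE parameters (`params`,
#'   and packed as `theta`), `cov` (free-parameter covariance), `loglik`,
#'   `converged`, subject/interval counts and the observed transition-count
#'   table.
#' @export
fit_msm <- function(spec, panel, init = "crude",
                    na_action = c("error", "omit"), control = list()) {
  na_action <- match.arg(na_action)
  ivd <- build_interval_data(spec, panel, na_action)
  K <- nrow(spec$transitions)
  lay <- cpp_layout(spec)

  # warn when a transition type is observed more rarely than the number of
  # free parameters attached to it
  n_free_k <- 1L + as.integer(spec$age_free) +
    if (length(spec$covariates)) rowSums(spec$free) else 0L
  for (k in seq_len(K)) {
    nk <- sum(ivd$from == lay$tfrom[k] & ivd$to == lay$tto[k])
    if (nk < n_free_k[k])
      warning("transition ", spec$transitions$label[k], " observed ", nk,
              " time(s), fewer than its ", n_free_k[k], " free parameters",
              call. = FALSE)
  }

  if (identical(init, "crude")) {
    theta0 <- c(crude_inits(spec, ivd), rep(0, sum(spec$age_free)),
                rep(0, sum(spec$free)))
  } else {
    stopifnot(inherits(init, "msm_params"))
    theta0 <- pack_params(spec, init)
  }
  names(theta0) <- param_names(spec)

  negll <- function(theta) {
    ll <- sum(interval_loglik_vec(spec, unpack_params(spec, theta), ivd))
    if (!is.finite(ll)) return(1e15)
    -ll
  }
  control <- modifyList(list(maxit = 500, reltol = 1e-10), control)

  opt <- tryCatch(optim(theta0, negll, method = "BFGS", control = control),
                  error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0 && is.finite(opt$value)
  theta <- if (!is.null(opt)) opt$par else theta0
  value <- if (!is.null(opt)) opt$value else negll(theta0)

  # Newton polish: at a quadratic optimum this reaches machine precision.
  # The Hessian is reused across the (at most two) steps and refreshed once
  # at the final iterate for the covariance.
  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  if (!is.null(H)) {
    moved <- FALSE
    for (it in 1:2) {
      g <- numeric_grad(negll, theta)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- theta - step
      vc <- negll(cand)
      if (is.finite(vc) && vc <= value + 1e-9) {
        theta <- cand; value <- vc; moved <- TRUE
        if (max(abs(step)) < 1e-8) break
      } else break
    }
    if (moved) H <- tryCatch(optimHess(theta, negll), error = function(e) H)
  }

  cov <- NULL
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      cov <- (cov + t(cov)) / 2
      if (any(!is.finite(cov)) || any(diag(cov) <= 0)) cov <- NULL
    }
  }
  if (is.null(cov)) converged <- FALSE

  tab <- table(factor(ivd$from, levels = seq_len(spec$state_space$n_alive) - 1L,
                      labels = spec$state_space$labels[-spec$state_space$death]),
               factor(ivd$to, levels = seq_len(spec$state_space$n_alive + 1L) - 1L,
                      labels = spec$state_space$labels[c(setdiff(
                        seq_len(spec$state_space$n_states),
                        spec$state_space$death), spec$state_space$death)]))

  structure(
    list(spec = spec, params = unpack_params(spec, theta), theta = theta,
         cov = cov, loglik = -value, converged = converged,
         n_subjects = ivd$n_subjects, n_intervals = length(ivd$a0),
         transition_counts = tab, init = theta0),
    class = "hwle_fit")
}

numeric_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' @export
print.hwle_fit <- function(x, digits = 4, ...) {
  cat("Multi-state model fit:", x$n_subjects, "subjects,", x$n_intervals,
      "observation intervals\n")
  cat("log-likelihood:", format(x$loglik, digits = 10),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  se <- if (!is.null(x$cov)) sqrt(diag(x$cov)) else rep(NA_real_,
                                                        length(x$theta))
  est <- data.frame(estimate = round(x$theta, digits),
                    se = round(se, digits))
  print(est)
  invisible(x)
}

#' Hazard-rate-ratio table for a fitted model
#'
#' One row per (transition, effect) with the age-adjusted hazard rate ratio
#' `exp(beta)` and 95% Wald interval `exp(beta +/- 1.96 se)`; covariate
#' effects constrained at HRR = 1 are reported as `"1.00 (fixed)"`.  Row
#' order follows the permitted transitions of the state space (for the
#' 3-state preset: HW-nHW, HW-dead, nHW-HW, nHW-dead), age first within each
#' transition, matching the conventional reporting layout.
#'
#' @param fit an `hwle_fit` (must have converged for interval columns; with a
#'   failed covariance the CIs are `NA` with a warning).
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `transition`, `effect`, `hrr`, `lcl`,
#'   `ucl`, `fixed`, `formatted`.
#' @export
hazard_ratio_table <- function(fit, conf = 0.95) {
  spec <- fit$spec
  K <- nrow(spec$transitions)
  z <- -qnorm((1 - conf) / 2)
  se <- rep(NA_real_, length(fit$theta))
  if (!is.null(fit$cov)) se <- sqrt(pmax(diag(fit$cov), 0)) else
    warning("covariance unavailable; confidence limits reported as missing")
  rows <- list()
  idx_age <- rep(NA_integer_, K)
  idx_age[spec$age_free] <- K + seq_len(sum(spec$age_free))
  free_idx <- matrix(NA_integer_, K, length(spec$covariates))
  if (any(spec$free))
    free_idx[spec$free] <- K + sum(spec$age_free) + seq_len(sum(spec$free))
  for (k in seq_len(K)) {
    lab <- spec$transitions$label[k]
    if (is.na(idx_age[k])) {
      rows[[length(rows) + 1L]] <- data.frame(
        transition = lab, effect = "age", hrr = 1,
        lcl = NA_real_, ucl = NA_real_, fixed = TRUE)
    } else {
      b <- fit$theta[idx_age[k]]; s <- se[idx_age[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        transition = lab, effect = "age", hrr = exp(b),
        lcl = exp(b - z * s), ucl = exp(b + z * s), fixed = FALSE)
    }
    for (j in seq_along(spec$covariates)) {
      if (spec$free[k, j]) {
        i <- free_idx[k, j]
        b <- fit$theta[i]; s <- se[i]
        rows[[length(rows) + 1L]] <- data.frame(
          transition = lab, effect = spec$covariates[j], hrr = exp(b),
          lcl = exp(b - z * s), ucl = exp(b + z * s), fixed = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          transition = lab, effect = spec$covariates[j], hrr = 1,
          lcl = NA_real_, ucl = NA_real_, fixed = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$formatted <- ifelse(
    out$fixed, "1.00 (fixed)",
    sprintf("%.2f (%.2f,%.2f)", out$hrr, out$lcl, out$ucl))
  out
}

#' Baseline transition intensities at the age origin
#'
#' @param fit an `hwle_fit`.
#' @return data.frame of per-transition baseline intensities (per year) at
#'   the spec's age origin with 95% Wald intervals on the log scale.
#' @export
baseline_intensities <- function(fit) {
  spec <- fit$spec
  K <- nrow(spec$transitions)
  se <- if (!is.null(fit$cov)) sqrt(pmax(diag(fit$cov)[seq_len(K)], 0))
        else rep(NA_real_, K)
  lq <- fit$theta[seq_len(K)]
  data.frame(transition = spec$transitions$label,
             q0 = exp(lq), lcl = exp(lq - 1.96 * se),
             ucl = exp(lq + 1.96 * se))
}

#' @importFrom stats qnorm
NULL
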