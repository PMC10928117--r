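#' Specify a transition-intensity model
#'
#' Defines the parametric model for the transition intensities: for each
#' permitted transition \eqn{r \to s},
#' \deqn{q_{rs}(t, x) = \exp\{\log q^0_{rs} + \beta^{age}_{rs}(t - a_0) +
#'   \textstyle\sum_k \beta_{rs,k} x_k\}}
#' with age origin \eqn{a_0} (50 by default).  Age is always included on
#' every permitted transition; binary covariates enter every transition
#' unless constrained.  A constraint fixes a covariate's effect on a
#' transition at zero on the log scale (hazard rate ratio 1), as is done for
#' workplace factors on transitions out of the not-healthy-and/or-not-working
#' state, where the factor is undefined for non-workers.
#'
#' @param space a [state_space()].
#' @param covariates character vector of binary covariate names.
#' @param constraints `NULL`, or a data.frame with columns `covariate`,
#'   `from`, `to` listing (transition, covariate) pairs fixed at HRR = 1.
#'   [fix_hrr()] builds rows conveniently.
#' @param fix_age `NULL` (age slope free on every transition, the standard
#'   model), `TRUE` (all slopes fixed at zero: the time-homogeneous
#'   submodel, useful for closed-form checks), or a data.frame with columns
#'   `from`, `to`.
#' @param age_origin age (years) at which baseline intensities apply.
#' @param step maximum sub-interval length (years) for the piecewise-constant
#'   age-inhomogeneity approximation used in likelihood and occupancy
#'   computations.
#' @return Object of class `msm_spec`.
#' @examples
#' sp <- msm_spec(hwle_states(3), covariates = "noauto",
#'                constraints = fix_hrr("noauto", from = 2, to = c(1, 3)))
#' @export
msm_spec <- function(space, covariates = character(), constraints = NULL,
                     age_origin = 50, step = 0.5, fix_age = NULL) {
  stopifnot(inherits(space, "state_space"), step > 0)
  tr <- transitions(space)
  K <- nrow(tr)
  p <- length(covariates)
  free <- matrix(TRUE, K, p, dimnames = list(tr$label, covariates))
  age_free <- rep(TRUE, K)
  if (isTRUE(fix_age)) age_free[] <- FALSE
  else if (!is.null(fix_age) && is.data.frame(fix_age))
    for (i in seq_len(nrow(fix_age))) {
      k <- which(tr$from == fix_age$from[i] & tr$to == fix_age$to[i])
      if (!length(k)) stop("fix_age references a non-permitted transition")
      age_free[k] <- FALSE
    }
  if (!is.null(constraints) && nrow(constraints)) {
    for (i in seq_len(nrow(constraints))) {
      k <- which(tr$from == constraints$from[i] & tr$to == constraints$to[i])
      if (!length(k))
        stop("constraint references a transition that is not permitted: ",
             constraints$from[i], "->", constraints$to[i])
      j <- match(constraints$covariate[i], covariates)
      if (is.na(j))
        stop("constraint references unknown covariate: ",
             constraints$covariate[i])
      free[k, j] <- FALSE
    }
  }
  structure(
    list(state_space = space, transitions = tr, covariates = covariates,
         free = free, age_free = age_free, age_origin = age_origin,
         step = step, n_params = K + sum(age_free) + sum(free)),
    class = "msm_spec")
}

#' @rdname msm_spec
#' @param covariate covariate name.
#' @param from,to state indices (recycled against each other) of the
#'   transitions on which the covariate effect is fixed at HRR = 1.
#' @export
fix_hrr <- function(covariate, from, to) {
  n <- max(length(from), length(to))
  data.frame(covariate = covariate, from = rep_len(from, n),
             to = rep_len(to, n), stringsAsFactors = FALSE)
}

#' @export
print.msm_spec <- function(x, ...) {
  cat("msm_spec:", nrow(x$transitions), "permitted transitions,",
      length(x$covariates), "covariate(s),", x$n_params, "free parameters\n")
  nfix <- sum(!x$free)
  if (nfix) cat(nfix, "covariate effect(s) fixed at HRR = 1\n")
  invisible(x)
}

#' Build a parameter set for a transition model
#'
#' @param spec an [msm_spec()].
#' @param logq0 numeric vector (length = number of permitted transitions, in
#'   [transitions()] order) of log baseline intensities at the age origin.
#' @param beta_age per-transition log-hazard age slopes (per year).
#' @param beta matrix (transition x covariate) of log hazard rate ratios;
#'   constrained entries are forced to zero.  May be omitted when the spec
#'   has no covariates.
#' @return Object of class `msm_params`.
#' @export
msm_params <- function(spec, logq0, beta_age, beta = NULL) {
  K <- nrow(spec$transitions)
  p <- length(spec$covariates)
  logq0 <- rep_len(as.numeric(logq0), K)
  beta_age <- rep_len(as.numeric(beta_age), K)
  if (is.null(beta)) beta <- matrix(0, K, p)
  if (!is.matrix(beta)) beta <- matrix(beta, K, p)
  stopifnot(all(dim(beta) == c(K, p)))
  beta[!spec$free] <- 0
  if (!all(is.finite(c(logq0, beta_age, beta))))
    stop("parameters must be finite")
  dimnames(beta) <- list(spec$transitions$label, spec$covariates)
  structure(list(logq0 = setNames(logq0, spec$transitions$label),
                 beta_age = setNames(beta_age, spec$transitions$label),
                 beta = beta),
            class = "msm_params")
}

# free-parameter packing: c(logq0, free age slopes, free betas
# column-major); pack/unpack form a bijection over the free parameters
pack_params <- function(spec, params) {
  c(params$logq0, params$beta_age[spec$age_free], params$beta[spec$free])
}

unpack_params <- function(spec, theta) {
  K <- nrow(spec$transitions)
  p <- length(spec$covariates)
  na <- sum(spec$age_free)
  ba <- rep(0, K)
  if (na) ba[spec$age_free] <- theta[K + seq_len(na)]
  beta <- matrix(0, K, p)
  if (any(spec$free)) beta[spec$free] <- theta[(K + na + 1):length(theta)]
  msm_params(spec, theta[1:K], ba, beta)
}

param_names <- function(spec) {
  lab <- spec$transitions$label
  nm <- paste0("logq0(", lab, ")")
  if (any(spec$age_free))
    nm <- c(nm, paste0("age(", lab[spec$age_free], ")"))
  if (any(spec$free)) {
    idx <- which(spec$free, arr.ind = TRUE)
    nm <- c(nm, paste0(spec$covariates[idx[, 2]], "(", lab[idx[, 1]], ")"))
  }
  nm
}

# covariate values (named list/vector) -> numeric vector in spec order;
# missing values are an error that points at the imputation module
covariate_vector <- function(spec, covariates) {
  p <- length(spec$covariates)
  if (p == 0L) return(numeric(0))
  if (is.null(covariates)) covariates <- setNames(rep(0, p), spec$covariates)
  x <- unlist(covariates)[spec$covariates]
  if (any(is.na(x)))
    stop("missing covariate value(s) for: ",
         paste(spec$covariates[is.na(x)], collapse = ", "),
         "; impute first (see pmm_impute)")
  as.numeric(x)
}

# eta_k = logq0_k + sum_j beta_kj x_j for a fixed covariate profile
eta_profile <- function(spec, params, covariates = NULL) {
  x <- covariate_vector(spec, covariates)
  as.numeric(params$logq0 + if (length(x)) params$beta %*% x else 0)
}

#' Generator (intensity) matrix at a given age and covariate profile
#'
#' Evaluates the full generator matrix Q: off-diagonal entries are the
#' transition intensities `q_rs(age, covariates)` for permitted transitions
#' (exactly zero elsewhere), each row sums to zero, and the death row is
#' identically zero.
#'
#' @param spec an [msm_spec()].
#' @param params an [msm_params()].
#' @param age age in years.
#' @param covariates named vector/list of binary covariate values (complete;
#'   missing values are an error).
#' @return `n_states x n_states` numeric matrix.
#' @examples
#' sp <- msm_spec(two_state_space())
#' pr <- msm_params(sp, logq0 = -2, beta_age = log(1.07))
#' build_generator(sp, pr, age = 50)[1, 2]  # exp(-2)
#' @export
build_generator <- function(spec, params, age, covariates = NULL) {
  if (age < spec$age_origin - 1e-8)
    stop("age must not precede the age origin (", spec$age_origin, ")")
  eta <- eta_profile(spec, params, covariates)
  S <- spec$state_space$n_states
  Q <- matrix(0, S, S, dimnames = list(spec$state_space$labels,
                                       spec$state_space$labels))
  tr <- spec$transitions
  q <- exp(eta + params$beta_age * (age - spec$age_origin))
  for (k in seq_len(nrow(tr))) Q[tr$from[k], tr$to[k]] <- q[k]
  diag(Q) <- -rowSums(Q)
  Q
}

#' A minimal alive/dead state space
#'
#' Convenience two-state space (one alive state, one absorbing death state)
#' used for closed-form checks of the likelihood and expectancy machinery.
#'
#' @return A [state_space()].
#' @export
two_state_space <- function() {
  allowed <- matrix(FALSE, 2, 2)
  allowed[1, 2] <- TRUE
  state_space("alive", allowed)
}

# map alive-state indices and transition endpoints to the 0-based layout the
# C++ kernel expects (death coded n_alive)
cpp_layout <- function(spec) {
  sp <- spec$state_space
  alive <- setdiff(seq_len(sp$n_states), sp$death)
  tr <- spec$transitions
  list(alive = alive,
       tfrom = match(tr$from, alive) - 1L,
       tto = ifelse(tr$to == sp$death, sp$n_alive,
                    match(tr$to, alive) - 1L),
       n_alive = sp$n_alive)
}

#' Interval transition probability matrix
#'
#' Computes `P(age0, age1)` for the age-inhomogeneous process by splitting
#' the interval into sub-intervals no longer than `step`, evaluating the
#' generator at each sub-interval's midpoint age, taking the matrix
#' exponential of each piece and composing in order.  Covariates are held
#' fixed over the interval (their value at the interval start).
#'
#' @inheritParams build_generator
#' @param age0,age1 interval endpoints (years), `age1 >= age0`.
#' @param step maximum sub-interval length; defaults to the spec's.
#' @return `n_states x n_states` stochastic matrix (rows sum to one).
#' @export
interval_probability <- function(spec, params, age0, age1, covariates = NULL,
                                 step = spec$step) {
  stopifnot(age1 >= age0, step > 0)
  eta <- eta_profile(spec, params, covariates)
  if (!all(is.finite(eta)) || !all(is.finite(params$beta_age)))
    stop("non-finite intensities")
  lay <- cpp_layout(spec)
  Pa <- cpp_pmat_alive(eta, as.numeric(params$beta_age), lay$tfrom, lay$tto,
                       lay$n_alive, age0, age1, spec$age_origin, step)
  S <- spec$state_space$n_states
  P <- matrix(0, S, S, dimnames = list(spec$state_space$labels,
                                       spec$state_space$labels))
  P[lay$alive, lay$alive] <- Pa
  P[lay$alive, spec$state_space$death] <- pmax(0, 1 - rowSums(Pa))
  P[spec$state_space$death, spec$state_space$death] <- 1
  P
}
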