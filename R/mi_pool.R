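# Multiple imputation of missing interview cells by predictive mean
# matching (PMM) across all waves simultaneously, and Rubin's-rules pooling
# with Barnard-Rubin degrees of freedom.

# Bayesian-perturbed linear regression + type-1 predictive mean matching:
# donors are scored with the least-squares coefficients, recipients with a
# posterior draw, and each missing cell receives an observed donor value
# drawn uniformly from the `donors` nearest by predicted value.
pmm_draw <- function(y, X, obs, mis, donors, ridge = 1e-6) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  p <- ncol(Xo)
  S <- crossprod(Xo) + diag(ridge, p)
  bhat <- solve(S, crossprod(Xo, yo))
  res <- yo - Xo %*% bhat
  df <- max(length(yo) - p, 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  Vchol <- chol(solve(S))
  bdot <- bhat + sqrt(sigma2) * (t(Vchol) %*% rnorm(p))
  yhat_obs <- as.numeric(Xo %*% bhat)
  yhat_mis <- as.numeric(X[mis, , drop = FALSE] %*% bdot)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    cand <- order(d + runif(length(d)) * 1e-10)[seq_len(min(donors,
                                                            length(d)))]
    yo[cand[sample.int(length(cand), 1)]]
  }, 0)
}

# reshape a long panel into a subjects x (variable.wave) working matrix;
# interview rows only (death records carry no items to impute)
panel_wide <- function(panel, aux_vars) {
  d <- panel$data
  sp <- panel$state_space
  interview <- is.na(d$state) | d$state != sp$death
  di <- d[interview, , drop = FALSE]
  di$wave <- stats::ave(seq_along(di$id), di$id, FUN = seq_along)
  ids <- unique(d$id)
  W <- max(di$wave)
  vars <- c("state", panel$covariates)
  cols <- list(baseline_age = setNames(rep(NA_real_, length(ids)), ids))
  for (a in aux_vars) cols[[a]] <- setNames(rep(NA_real_, length(ids)), ids)
  for (v in vars) for (w in seq_len(W))
    cols[[paste0(v, ".", w)]] <- setNames(rep(NA_real_, length(ids)), ids)
  for (w in seq_len(W)) {
    rows <- di[di$wave == w, , drop = FALSE]
    if (w == 1L) {
      cols$baseline_age[rows$id] <- rows$age
      for (a in aux_vars) cols[[a]][rows$id] <- as.numeric(rows[[a]])
    }
    for (v in vars)
      cols[[paste0(v, ".", w)]][rows$id] <- as.numeric(rows[[v]])
  }
  M <- do.call(cbind, cols)
  rownames(M) <- ids
  list(M = M, waves = W, vars = vars, interview = interview, long = di)
}

#' Multiple imputation by predictive mean matching across waves
#'
#' Imputes missing states and covariates at interviews by chained equations
#' on the wide (all-waves-simultaneously) data matrix: each incomplete
#' variable is regressed on every other variable-wave column, baseline age
#' and the auxiliary variables among its complete cases, regression
#' coefficients are perturbed by a posterior draw per imputation, and each
#' missing cell receives the observed value of one of the `donors` nearest
#' complete cases by predicted value.  Because donors are observed values,
#' imputed binary covariates stay in {0, 1} and imputed states stay valid
#' state codes.  Cells that are structurally absent (after death or
#' censoring) are never imputed.  Deterministic given `seed`.
#'
#' @param panel a [cohort_panel()] with missing interview cells.
#' @param aux_vars names of fully-observed auxiliary columns in the panel
#'   used as additional predictors (e.g. response-propensity proxies).
#' @param M number of imputed datasets (default 20).
#' @param donors donor-pool size for the matching step (default 5).
#' @param cycles chained-equation passes over the incomplete variables
#'   (default 10).
#' @param seed integer RNG seed (required).
#' @return Object of class `imputation_set`: `panels` (list of M completed
#'   `cohort_panel`s, identical to the input except at originally-missing
#'   cells), `M`, `aux_vars`, `seed`, `missing_counts`, and per-imputation
#'   summaries of the imputed values (`diagnostics`).
#' @export
pmm_impute <- function(panel, aux_vars = character(), M = 20, donors = 5,
                       cycles = 10, seed) {
  if (missing(seed)) stop("'seed' is required for reproducible imputations")
  stopifnot(M >= 1, donors >= 1)
  wd <- panel_wide(panel, aux_vars)
  X <- wd$M
  target_cols <- grep("\\.", colnames(X))
  miss_mask <- is.na(X)
  # structural gaps: subject not interviewed at that wave (death/censoring).
  # A cell is imputable only if the subject has an interview row at the wave.
  has_wave <- !is.na(X[, grep("^state\\.", colnames(X)), drop = FALSE])
  # state.w observed => wave exists; but state itself may be the missing item.
  # Reconstruct wave presence from the long data instead:
  di <- wd$long
  present <- matrix(FALSE, nrow(X), wd$waves,
                    dimnames = list(rownames(X), NULL))
  present[cbind(match(di$id, rownames(X)), di$wave)] <- TRUE
  imputable <- miss_mask
  for (cl in target_cols) {
    w <- as.integer(sub(".*\\.", "", colnames(X)[cl]))
    imputable[, cl] <- miss_mask[, cl] & present[, w]
  }
  imputable[, setdiff(seq_len(ncol(X)), target_cols)] <- FALSE
  missing_counts <- colSums(imputable)

  no_cc <- colnames(X)[vapply(seq_len(ncol(X)), function(j)
    any(imputable[, j]) && !any(!is.na(X[, j])), TRUE)]
  if (length(no_cc))
    stop("variable(s) with no complete cases cannot be imputed: ",
         paste(no_cc, collapse = ", "))

  incomplete <- which(missing_counts > 0)
  # visit order: closest to monotone (fewest missing first)
  incomplete <- incomplete[order(missing_counts[incomplete])]

  if (length(incomplete) == 0L) {
    panels <- replicate(M, panel, simplify = FALSE)
    return(structure(list(panels = panels, M = M, aux_vars = aux_vars,
                          seed = seed, missing_counts = missing_counts,
                          diagnostics = NULL),
                     class = "imputation_set"))
  }

  set.seed(seed)
  # working matrix: structural NAs filled (last value carried forward within
  # subject-variable, then column mean) so they can serve as predictors;
  # these fills never leave the working matrix
  fill_structural <- function(Xw) {
    for (v in wd$vars) {
      colsv <- grep(paste0("^", v, "\\."), colnames(Xw))
      vals <- Xw[, colsv, drop = FALSE]
      for (w in seq_len(ncol(vals))[-1]) {
        na <- is.na(vals[, w])
        vals[na, w] <- vals[na, w - 1]
      }
      Xw[, colsv] <- vals
    }
    for (j in seq_len(ncol(Xw))) {
      na <- is.na(Xw[, j])
      if (any(na)) Xw[na, j] <- mean(Xw[, j], na.rm = TRUE)
    }
    Xw
  }

  diag_rows <- list()
  panels <- vector("list", M)
  for (m in seq_len(M)) {
    Xw <- X
    # initialise genuinely-missing cells by random draws from observed values
    for (j in incomplete) {
      obs_vals <- X[!is.na(X[, j]), j]
      n_mis <- sum(imputable[, j])
      Xw[imputable[, j], j] <- sample(obs_vals, n_mis, replace = TRUE)
    }
    Xw <- fill_structural(Xw)
    for (cyc in seq_len(cycles)) {
      for (j in incomplete) {
        obs <- !is.na(X[, j])
        mis <- imputable[, j]
        pred <- cbind(1, Xw[, -j, drop = FALSE])
        Xw[mis, j] <- pmm_draw(ifelse(obs, X[, j], Xw[, j]), pred,
                               obs, mis, donors)
      }
    }
    # write imputed cells back into the long panel
    d <- panel$data
    for (j in incomplete) {
      nm <- colnames(X)[j]
      v <- sub("\\..*", "", nm)
      w <- as.integer(sub(".*\\.", "", nm))
      subj <- rownames(X)[imputable[, j]]
      rows <- di[di$wave == w & di$id %in% subj, , drop = FALSE]
      long_idx <- match(paste(rows$id, rows$age), paste(d$id, d$age))
      vals <- Xw[rows$id, j]
      if (v == "state") vals <- as.integer(round(vals))
      d[[v]][long_idx] <- vals
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(imputation = m, variable = nm, n_imputed = length(vals),
                   mean_imputed = mean(vals))
    }
    pm <- panel
    pm$data <- d
    panels[[m]] <- pm
  }
  structure(list(panels = panels, M = M, aux_vars = aux_vars, seed = seed,
                 missing_counts = missing_counts,
                 diagnostics = do.call(rbind, diag_rows)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set: M =", x$M, "completed panels\n")
  mc <- x$missing_counts[x$missing_counts > 0]
  if (length(mc))
    cat("imputed cells:", paste(names(mc), mc, sep = "=", collapse = ", "),
        "\n")
  else cat("no missing cells (identical copies)\n")
  invisible(x)
}

#' Fit the model (and optionally expectancies) on each imputed dataset
#'
#' Convergence failures are recorded per imputation, not fatal: failed fits
#' are flagged and excluded by the pooling functions.
#'
#' @param imps an [pmm_impute()] result.
#' @param spec an [msm_spec()].
#' @param expectancy `NULL`, or a list of settings
#'   (`init_dist`, `covariates`, `n_draws`, `seed`, `start_age`, `max_age`,
#'   `h`) forwarded to [expectancy_uncertainty()] per imputation.
#' @param ... passed to [fit_msm()].
#' @return Object of class `mi_runs`: `fits` (list), `converged` (logical
#'   vector), and optionally `expectancies`.
#' @export
run_per_imputation <- function(imps, spec, expectancy = NULL, ...) {
  fits <- vector("list", imps$M)
  exps <- if (is.null(expectancy)) NULL else vector("list", imps$M)
  converged <- logical(imps$M)
  for (m in seq_len(imps$M)) {
    fits[[m]] <- tryCatch(fit_msm(spec, imps$panels[[m]], ...),
                          error = function(e) NULL)
    converged[m] <- !is.null(fits[[m]]) && isTRUE(fits[[m]]$converged)
    if (!is.null(expectancy) && converged[m]) {
      e <- expectancy
      id <- if (is.null(e$init_dist))
        initial_state_distribution(imps$panels[[m]]) else e$init_dist
      exps[[m]] <- tryCatch(
        expectancy_uncertainty(fits[[m]], id, covariates = e$covariates,
                               n_draws = e$n_draws %||% 200,
                               seed = (e$seed %||% imps$seed) + m,
                               start_age = e$start_age %||% 50,
                               max_age = e$max_age %||% 120,
                               h = e$h %||% 0.25),
        error = function(err) NULL)
    }
  }
  if (!any(converged)) stop("no imputation fit converged")
  structure(list(fits = fits, converged = converged, expectancies = exps,
                 M = imps$M),
            class = "mi_runs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Barnard-Rubin adjusted degrees of freedom
#'
#' Small-sample reference degrees of freedom for multiply-imputed inference.
#' With an (effectively) infinite complete-data df this reduces to the
#' classical \eqn{(m - 1) / \lambda^2}.
#'
#' @param m number of imputations pooled.
#' @param b between-imputation variance.
#' @param t total variance.
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @return degrees of freedom (positive).
#' @export
barnard_rubin <- function(m, b, t, dfcom = Inf) {
  lambda <- (1 + 1 / m) * b / t
  lambda <- max(lambda, 1e-8)
  dfold <- (m - 1) / lambda^2
  if (!is.finite(dfcom)) return(dfold)
  dfobs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
  dfold * dfobs / (dfold + dfobs)
}

#' Pool a scalar estimate across imputations by Rubin's rules
#'
#' Point estimate = mean of the per-imputation points; between-imputation
#' variance = their sample variance; total variance =
#' `within + (1 + 1/m) * between`; 95% CI uses a t reference with
#' [barnard_rubin()] degrees of freedom.  Log-scale quantities (hazard rate
#' ratios) should be pooled on the log scale and exponentiated afterwards;
#' expectancies are pooled on the raw scale.
#'
#' @param points per-imputation point estimates (length >= 2).
#' @param variances per-imputation (within-imputation) variances, same
#'   length.
#' @param dfcom complete-data degrees of freedom for [barnard_rubin()].
#' @return Object of class `pooled_scalar`: `point`, `within_var`,
#'   `between_var`, `total_var`, `df`, `ci95`, `m_used`.
#' @export
rubin_pool <- function(points, variances, dfcom = Inf) {
  if (length(points) != length(variances))
    stop("'points' and 'variances' must have equal length")
  if (length(points) < 2)
    stop("pooling requires at least two imputations (no between-variance)")
  m <- length(points)
  qbar <- mean(points)
  b <- var(points)
  ubar <- mean(variances)
  tv <- ubar + (1 + 1 / m) * b
  df <- barnard_rubin(m, b, tv, dfcom)
  half <- qt(0.975, df) * sqrt(tv)
  structure(list(point = qbar, within_var = ubar, between_var = b,
                 total_var = tv, df = df,
                 ci95 = c(qbar - half, qbar + half), m_used = m),
            class = "pooled_scalar")
}

#' @export
print.pooled_scalar <- function(x, ...) {
  cat(sprintf("pooled: %.4f (95%% CI %.4f, %.4f); total var %.5f, df %.1f, m = %d\n",
              x$point, x$ci95[1], x$ci95[2], x$total_var, x$df, x$m_used))
  invisible(x)
}

#' Pool hazard-rate-ratio tables across imputations
#'
#' Pools each free log-HRR (and log baseline intensity) across the converged
#' imputation fits on the log scale and exponentiates, yielding the usual
#' reporting table with an `m_used` column.  Non-converged fits are excluded.
#'
#' @param runs an [run_per_imputation()] result.
#' @param dfcom complete-data df for [barnard_rubin()].
#' @return data.frame: `param`, `hrr`, `lcl`, `ucl`, `m_used`.
#' @export
pool_fits <- function(runs, dfcom = Inf) {
  keep <- which(runs$converged)
  if (length(keep) < 2) stop("need at least two converged fits to pool")
  fits <- runs$fits[keep]
  nm <- names(fits[[1]]$theta)
  out <- lapply(seq_along(nm), function(i) {
    pts <- vapply(fits, function(f) f$theta[i], 0)
    vrs <- vapply(fits, function(f) diag(f$cov)[i], 0)
    pl <- rubin_pool(pts, vrs, dfcom)
    data.frame(param = nm[i], hrr = exp(pl$point),
               lcl = exp(pl$ci95[1]), ucl = exp(pl$ci95[2]),
               m_used = pl$m_used)
  })
  do.call(rbind, out)
}

#' Pool expectancy estimates across imputations
#'
#' Expectancies are pooled on the raw (years) scale; the within-imputation
#' variance is each imputation's Monte-Carlo variance over its parameter
#' draws.  Non-converged imputations are excluded.
#'
#' @param runs an [run_per_imputation()] result produced with expectancy
#'   settings.
#' @param dfcom complete-data df.
#' @return data.frame: `state`, `point`, `low`, `high`, `m_used`.
#' @export
pool_expectancies <- function(runs, dfcom = Inf) {
  keep <- which(runs$converged & !vapply(runs$expectancies, is.null, TRUE))
  if (length(keep) < 2) stop("need at least two converged fits to pool")
  exps <- runs$expectancies[keep]
  labs <- exps[[1]]$table$state
  out <- lapply(seq_along(labs), function(i) {
    pts <- vapply(exps, function(e) e$table$point[i], 0)
    vrs <- vapply(exps, function(e) var(e$draws[, i]), 0)
    pl <- rubin_pool(pts, vrs, dfcom)
    data.frame(state = labs[i], point = pl$point, low = pl$ci95[1],
               high = pl$ci95[2], m_used = pl$m_used)
  })
  do.call(rbind, out)
}
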