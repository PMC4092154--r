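# Zero-inflated Poisson GAM machinery.
#
# The response is modeled as a two-state mixture: with probability p_i the
# cruise is in the "regular" state and the catch is Poisson(mu_i) with
# log mu_i = log(effort) + additive smooth/factor terms; with probability
# 1 - p_i the cruise is in the structural-zero state. p_i is the probability
# of the REGULAR (non-zero-inflated) state throughout. GAM fixes p = 1;
# ZIGAM gives p its own logit-linear additive model; COZIGAM constrains
# logit(p_i) = alpha + delta * log(mu_i).

# Observed-data mixture log-likelihood.
zip_obs_ll <- function(y, eta, zeta) {
  eta <- clip_lp(eta)
  mu <- exp(eta)
  p <- stats::plogis(clip_lp(zeta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(y == 0,
             log((1 - p) + p * exp(-mu)),
             log(p) + y * eta - mu - lgamma(y + 1)))
}

# Mixture saturated log-likelihood (p_i = 1 and mu_i = y_i at positives;
# structural zero with probability one at zeros). Shared by all model types.
mixture_sat_ll <- function(y) {
  yp <- y[y > 0]
  sum(yp * log(yp) - yp - lgamma(yp + 1))
}

# Intercept-only mixture fit (2 parameters), the common null model for
# deviance-explained of zero-inflated fits.
mixture_null_ll <- function(y, offset) {
  f <- function(th) -zip_obs_ll(y, th[1] + offset, th[2])
  start <- c(log(max(mean(y / exp(offset)), 1e-8)),
             stats::qlogis(min(max(mean(y > 0) + 0.05, 0.05), 0.95)))
  opt <- stats::optim(start, f, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  -opt$value
}

# Analytic negative Hessian of the penalized observed-data log-likelihood of
# a ZIGAM at (beta, gamma); parameter order (count, zero).
zigam_neg_hessian <- function(y, Xc, Xz, beta, gamma, offset, Sc, Sz) {
  eta <- clip_lp(drop(Xc %*% beta) + offset)
  zeta <- clip_lp(drop(Xz %*% gamma))
  mu <- exp(eta)
  p <- pmin(pmax(stats::plogis(zeta), 1e-12), 1 - 1e-12)
  q <- p * (1 - p)
  z0 <- y == 0
  d_hh <- d_zz <- d_hz <- numeric(length(y))
  # positive observations: independent Poisson and Bernoulli contributions
  d_hh[!z0] <- -mu[!z0]
  d_zz[!z0] <- -q[!z0]
  if (any(z0)) {
    E <- exp(-mu[z0]); pz <- p[z0]; qz <- q[z0]; muz <- mu[z0]
    A <- pz * E
    L <- (1 - pz) + A
    d_hh[z0] <- A * muz * (muz - 1) / L - (A * muz / L)^2
    d_zz[z0] <- qz * (1 - 2 * pz) * (E - 1) / L - (qz * (E - 1) / L)^2
    d_hz[z0] <- -muz * qz * E / L + A * muz * qz * (E - 1) / L^2
  }
  H11 <- -crossprod(Xc, Xc * d_hh) + Sc
  H22 <- -crossprod(Xz, Xz * d_zz) + Sz
  H12 <- -crossprod(Xc, Xz * d_hz)
  rbind(cbind(H11, H12), cbind(t(H12), H22))
}

# Log-determinant with ridge stabilization for a numerically singular Hessian.
safe_logdet <- function(H) {
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) {
    warning("singular Hessian in Laplace evidence; ridge-stabilized")
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    ridge <- max(abs(ev)) * 1e-8 + max(0, -min(ev)) + 1e-10
    R <- chol(H + diag(ridge, nrow(H)))
  }
  2 * sum(log(diag(R)))
}

# Laplace evidence given the penalized log-likelihood at the mode, the
# negative Hessian of the penalized log-likelihood, and the sum of the
# penalty-prior normalizing constants. Flat improper priors on unpenalized
# coefficients; identical conventions for GAM, ZIGAM and COZIGAM.
laplace_logE_core <- function(l_pen, H, prior_const) {
  l_pen + 0.5 * nrow(H) * log(2 * pi) - 0.5 * safe_logdet(H) + prior_const
}

# EM fit of a ZIGAM at fixed smoothing parameters.
zigam_em <- function(y, cdes, zdes, lam_c, lam_z, offset, init = NULL,
                     maxit = 250, tol = 1e-6) {
  Sc <- component_penalty(cdes, lam_c)
  Sz <- component_penalty(zdes, lam_z)
  pos <- y > 0
  if (is.null(init)) {
    z <- ifelse(pos, 1, 0.3)
    beta <- NULL; gamma <- NULL
  } else {
    eta <- clip_lp(drop(cdes$X %*% init$beta) + offset)
    zeta <- clip_lp(drop(zdes$X %*% init$gamma))
    mu <- exp(eta); p <- stats::plogis(zeta)
    z <- ifelse(pos, 1, pmin(pmax(
      p * exp(-mu) / ((1 - p) + p * exp(-mu)), 1e-10), 1 - 1e-10))
    beta <- init$beta; gamma <- init$gamma
  }
  trace <- numeric(0)
  pll_old <- -Inf
  converged <- FALSE
  cfit <- zfit <- NULL
  it <- 0
  while (it < maxit) {
    it <- it + 1
    cfit <- tryCatch(
      fit_penalized_glm(y, cdes$X, Sc, offset, "poisson", weights = z,
                        beta_init = beta),
      pirls_convergence_error = function(e) e$last_fit)
    zfit <- tryCatch(
      fit_penalized_glm(z, zdes$X, Sz, 0, "binomial", beta_init = gamma),
      pirls_convergence_error = function(e) e$last_fit)
    beta <- cfit$beta; gamma <- zfit$beta
    eta <- cfit$eta
    zeta <- zfit$eta
    mu <- exp(eta); p <- stats::plogis(zeta)
    z <- ifelse(pos, 1, pmin(pmax(
      p * exp(-mu) / ((1 - p) + p * exp(-mu)), 1e-10), 1 - 1e-10))
    pll <- zip_obs_ll(y, eta, zeta) -
      0.5 * sum(beta * drop(Sc %*% beta)) -
      0.5 * sum(gamma * drop(Sz %*% gamma))
    trace <- c(trace, pll)
    if (is.finite(pll_old) &&
        abs(pll - pll_old) < tol * (abs(pll_old) + 1)) {
      converged <- TRUE
      break
    }
    pll_old <- pll
  }
  list(beta = beta, gamma = gamma, cfit = cfit, zfit = zfit, z = z,
       eta = eta, zeta = zeta, mu = mu, p = p,
       ll_obs = zip_obs_ll(y, eta, zeta),
       pll_obs = trace[length(trace)], trace = trace,
       Sc = Sc, Sz = Sz, iterations = it, converged = converged)
}

# Coordinate-wise grid maximization of logE over log-lambda. `evalf(lam)`
# returns list(logE = ..., state = ...); warm state is threaded through.
select_lambdas <- function(evalf, n_lam, grid, passes = NULL) {
  if (n_lam == 0) {
    r <- evalf(numeric(0), NULL)
    return(list(lambdas = numeric(0), logE = r$logE, state = r$state))
  }
  if (is.null(passes)) passes <- if (n_lam > 1) 2 else 1
  lam <- rep(1, n_lam)
  state <- NULL
  r <- evalf(lam, state)
  best <- r$logE; state <- r$state
  for (pass in seq_len(passes)) {
    for (j in seq_len(n_lam)) {
      for (g in grid) {
        if (g == lam[j]) next
        cand <- lam; cand[j] <- g
        r <- tryCatch(evalf(cand, state), error = function(e) NULL)
        if (!is.null(r) && is.finite(r$logE) && r$logE > best + 1e-8) {
          best <- r$logE; lam <- cand; state <- r$state
        }
      }
    }
  }
  list(lambdas = lam, logE = best, state = state)
}

default_lambda_grid <- function() 10^seq(-2, 4, by = 1)

# Shared pre-fit validation/preparation: response, offset, complete cases.
prepare_fit_data <- function(spec, data) {
  vars <- unique(c(spec$response, spec$offset, spec$factor_terms,
                   unlist(lapply(spec$smooth_terms, `[[`, "vars"))))
  zt <- resolve_zero_terms(spec)
  vars <- unique(c(vars, zt$factor_terms,
                   unlist(lapply(zt$smooth_terms, `[[`, "vars"))))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop(sprintf("columns not found in data: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!all(cc)) {
    warning(sprintf("dropping %d rows with missing model covariates",
                    sum(!cc)))
    data <- data[cc, , drop = FALSE]
  }
  y <- data[[spec$response]]
  if (any(y < 0) || any(y != round(y))) {
    stop("response must contain non-negative integer counts")
  }
  eff <- data[[spec$offset]]
  if (any(eff <= 0)) stop("offset (effort) column must be strictly positive")
  list(data = data, y = as.numeric(y), offset = log(eff))
}

resolve_zero_terms <- function(spec) {
  zt <- spec$zero_terms
  if (identical(zt, "mirror")) {
    list(smooth_terms = spec$smooth_terms, factor_terms = spec$factor_terms)
  } else if (identical(zt, "intercept")) {
    list(smooth_terms = list(), factor_terms = character())
  } else if (is.list(zt)) {
    list(smooth_terms = if (is.null(zt$smooth_terms)) list() else zt$smooth_terms,
         factor_terms = if (is.null(zt$factor_terms)) character() else zt$factor_terms)
  } else stop("invalid zero_terms")
}

new_zs_fit <- function(...) structure(list(...), class = "zs_fit")

#' @export
print.zs_fit <- function(x, ...) {
  cat(sprintf("%s fit of '%s': n = %d, logE = %.3f, edf = %.2f,\n",
              x$spec$model_type, x$spec$response, x$n, x$logE, x$edf_total))
  cat(sprintf("  dev.expl = %.1f%%, R2.adj = %.3f, EM iterations = %d%s\n",
              100 * x$dev_expl, x$r2_adj, x$em_iterations,
              if (x$converged) "" else " (NOT converged)"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Fit a Poisson GAM of catch counts with a log-effort offset
#'
#' Penalized-likelihood Poisson additive model; smoothing parameters are
#' chosen by maximizing the same Laplace-approximated log marginal likelihood
#' (logE) used for model comparison, so that smoothness selection and model
#' selection live on one scale.
#'
#' @param spec a [model_spec()] with `model_type = "GAM"`.
#' @param data cruise-level data frame (see [aggregate_by_cruise()] or
#'   [default_scenario()]).
#' @param lambdas optional fixed smoothing parameters (one per smooth term);
#'   when `NULL` they are optimized over `lambda_grid` coordinate-wise.
#' @param lambda_grid candidate smoothing-parameter grid.
#' @return a `zs_fit` object; see the package vignette for the field
#'   descriptions (coefficients, per-term edf, `logE`, `dev_expl`, `r2_adj`,
#'   posterior covariance).
#' @export
fit_gam <- function(spec, data, lambdas = NULL,
                    lambda_grid = default_lambda_grid()) {
  stopifnot(inherits(spec, "ModelSpec"), spec$model_type == "GAM")
  pd <- prepare_fit_data(spec, data)
  y <- pd$y; offset <- pd$offset; data <- pd$data
  if (all(y == 0)) warning("degenerate fit: all-zero response; intercept guarded")
  cdes <- build_component_design(data, spec$smooth_terms, spec$factor_terms)
  nlam <- length(cdes$smooth_ix)
  evalf <- function(lam, state) {
    Sc <- component_penalty(cdes, lam)
    ft <- tryCatch(
      fit_penalized_glm(y, cdes$X, Sc, offset, "poisson",
                        beta_init = if (!is.null(state)) state$beta else NULL),
      pirls_convergence_error = function(e) e$last_fit)
    logE <- laplace_logE_core(ft$pll, ft$H, penalty_prior_const(cdes, lam))
    list(logE = logE, state = list(beta = ft$beta, fit = ft, lam = lam))
  }
  if (is.null(lambdas)) {
    sel <- select_lambdas(evalf, nlam, lambda_grid)
  } else {
    if (length(lambdas) != nlam) stop("need one lambda per smooth term")
    r <- evalf(lambdas, NULL)
    sel <- list(lambdas = lambdas, logE = r$logE, state = r$state)
  }
  ft <- sel$state$fit
  l_sat <- mixture_sat_ll(y)
  b0 <- log(max(sum(y) / sum(exp(offset)), 1e-13))
  l_null <- poisson_ll(y, rep(clip_lp(b0), length(y)) + offset)
  dev_expl <- if (l_sat - l_null > 1e-12) {
    1 - (l_sat - ft$ll) / (l_sat - l_null)
  } else 0
  n <- length(y)
  edf_total <- ft$edf
  assemble_fit(spec, data, n, cdes, NULL, ft$beta, NULL,
               lambdas = named_lambdas(sel$lambdas, cdes, NULL),
               logE = sel$logE, ll_obs = ft$ll, Vb = ft$Vb,
               edf_diag_c = ft$edf_diag, edf_diag_z = NULL,
               dev_expl = dev_expl, em_iterations = ft$iterations,
               converged = ft$converged, em_trace = NULL,
               mu = ft$mu, p = rep(1, n), offset = offset)
}

named_lambdas <- function(lam, cdes, zdes) {
  nms <- character(0)
  if (!is.null(cdes) && length(cdes$smooth_ix)) {
    nms <- c(nms, paste0("count:", vapply(
      cdes$blocks[cdes$smooth_ix], `[[`, "", "label")))
  }
  if (!is.null(zdes) && length(zdes$smooth_ix)) {
    nms <- c(nms, paste0("zero:", vapply(
      zdes$blocks[zdes$smooth_ix], `[[`, "", "label")))
  }
  stats::setNames(lam, nms)
}

# Common FittedModel assembly: per-term edf, R2_adj, joint covariance.
assemble_fit <- function(spec, data, n, cdes, zdes, beta, gamma, lambdas,
                         logE, ll_obs, Vb, edf_diag_c, edf_diag_z, dev_expl,
                         em_iterations, converged, em_trace, mu, p, offset,
                         alpha = NULL, delta = NULL, note = NULL,
                         extra_edf = 0) {
  edf <- numeric(0)
  for (b in cdes$blocks) {
    edf[paste0("count:", b$label)] <- if (is.null(edf_diag_c)) b$ncol else
      sum(edf_diag_c[b$idx])
  }
  if (!is.null(zdes)) {
    for (b in zdes$blocks) {
      edf[paste0("zero:", b$label)] <- if (is.null(edf_diag_z)) b$ncol else
        sum(edf_diag_z[b$idx])
    }
  }
  edf_total <- sum(edf) + extra_edf
  r2_dev <- dev_expl
  r2_adj <- 1 - ((n - 1) / max(n - edf_total, 1)) * (1 - r2_dev)
  new_zs_fit(spec = spec, n = n, data = data, beta = beta, gamma = gamma,
             alpha = alpha, delta = delta, lambdas = lambdas, edf = edf,
             edf_total = edf_total, logE = logE, ll_obs = ll_obs,
             r2_adj = r2_adj, dev_expl = dev_expl, posterior_cov = Vb,
             em_iterations = em_iterations, converged = converged,
             em_trace = em_trace, fitted_mu = mu, fitted_p = p,
             count_design = cdes, zero_design = zdes, offset = offset,
             note = note)
}

#' Fit a zero-inflated Poisson GAM by the EM algorithm
#'
#' Maximizes the mixture likelihood
#' \deqn{L = \prod_{y_i = 0}\{(1-p_i) + p_i e^{-\mu_i}\} \prod_{y_i > 0}
#'   p_i \,\mathrm{Pois}(y_i;\mu_i)}
#' by EM: the E-step computes responsibilities
#' \eqn{z_i = p_i e^{-\mu_i} / ((1-p_i) + p_i e^{-\mu_i})} for zero
#' observations (1 otherwise), and the M-step performs a weighted penalized
#' Poisson fit (weights \eqn{z_i}) plus a penalized binomial fit to the
#' fractional responses \eqn{z_i}. Iteration stops when the relative change in
#' the observed-data penalized log-likelihood falls below `tol`, or after
#' `maxit` (default 250) iterations with the convergence flag set to `FALSE`.
#' `p_i` is the probability of the regular (non-zero-inflated) state.
#'
#' @inheritParams fit_gam
#' @param spec a [model_spec()] with `model_type = "ZIGAM"`.
#' @param maxit EM iteration cap.
#' @param tol relative observed-data penalized log-likelihood tolerance.
#' @return a `zs_fit`; `em_trace` holds the observed-data penalized
#'   log-likelihood after every EM iteration (non-decreasing).
#' @export
fit_zigam <- function(spec, data, lambdas = NULL,
                      lambda_grid = default_lambda_grid(),
                      maxit = 250, tol = 1e-6) {
  stopifnot(inherits(spec, "ModelSpec"), spec$model_type == "ZIGAM")
  pd <- prepare_fit_data(spec, data)
  y <- pd$y; offset <- pd$offset; data <- pd$data
  if (!any(y == 0)) {
    gspec <- spec; gspec$model_type <- "GAM"; gspec$zero_terms <- "intercept"
    g <- fit_gam(gspec, data, lambdas = lambdas, lambda_grid = lambda_grid)
    g$spec <- spec
    g$note <- "no zeros in response: ZIGAM reduces to a Poisson GAM with p = 1"
    return(g)
  }
  zt <- resolve_zero_terms(spec)
  cdes <- build_component_design(data, spec$smooth_terms, spec$factor_terms)
  zdes <- build_component_design(data, zt$smooth_terms, zt$factor_terms)
  n_c <- length(cdes$smooth_ix); n_z <- length(zdes$smooth_ix)
  evalf <- function(lam, state) {
    em <- zigam_em(y, cdes, zdes, lam[seq_len(n_c)],
                   lam[n_c + seq_len(n_z)], offset,
                   init = state, maxit = maxit, tol = tol)
    H <- zigam_neg_hessian(y, cdes$X, zdes$X, em$beta, em$gamma, offset,
                           em$Sc, em$Sz)
    logE <- laplace_logE_core(em$pll_obs, H,
                              penalty_prior_const(cdes, lam[seq_len(n_c)]) +
                                penalty_prior_const(zdes, lam[n_c + seq_len(n_z)]))
    list(logE = logE, state = list(beta = em$beta, gamma = em$gamma,
                                   em = em, H = H))
  }
  if (is.null(lambdas)) {
    sel <- select_lambdas(evalf, n_c + n_z, lambda_grid)
  } else {
    if (length(lambdas) != n_c + n_z) {
      stop(sprintf("need %d lambdas (count smooths then zero smooths)",
                   n_c + n_z))
    }
    r <- evalf(lambdas, NULL)
    sel <- list(lambdas = lambdas, logE = r$logE, state = r$state)
  }
  em <- sel$state$em
  Vb <- tryCatch(chol2inv(chol(sel$state$H)), error = function(e)
    solve(sel$state$H + diag(mean(diag(sel$state$H)) * 1e-8,
                             nrow(sel$state$H))))
  l_sat <- mixture_sat_ll(y)
  l_null <- mixture_null_ll(y, offset)
  dev_expl <- if (l_sat - l_null > 1e-12) {
    1 - (l_sat - em$ll_obs) / (l_sat - l_null)
  } else 0
  assemble_fit(spec, data, length(y), cdes, zdes, em$beta, em$gamma,
               lambdas = named_lambdas(sel$lambdas, cdes, zdes),
               logE = sel$logE, ll_obs = em$ll_obs, Vb = Vb,
               edf_diag_c = em$cfit$edf_diag, edf_diag_z = em$zfit$edf_diag,
               dev_expl = dev_expl, em_iterations = em$iterations,
               converged = em$converged, em_trace = em$trace,
               mu = em$mu, p = em$p, offset = offset)
}

#' Fit a constrained zero-inflated Poisson GAM (COZIGAM)
#'
#' Same mixture likelihood as [fit_zigam()] but with the regular-state
#' probability coupled to the count mean through
#' \eqn{\mathrm{logit}(p_i) = \alpha + \delta \log \mu_i}. The linkage
#' constants (alpha, delta) are estimated jointly with the count-component
#' coefficients inside the EM M-step, which maximizes the expected
#' complete-data penalized log-likelihood by quasi-Newton ascent (a
#' generalized EM step, so the observed-data penalized log-likelihood is
#' still non-decreasing). The Laplace evidence uses a numerical Hessian of
#' the penalized observed-data log-likelihood in (beta, alpha, delta).
#'
#' @inheritParams fit_zigam
#' @param spec a [model_spec()] with `model_type = "COZIGAM"`.
#' @param fix_delta optionally fix the slope delta (e.g. `0` for an
#'   intercept-only zero model, the constant-p ZIGAM nesting case).
#' @return a `zs_fit` with linkage constants in `alpha` and `delta`.
#' @export
fit_cozigam <- function(spec, data, lambdas = NULL,
                        lambda_grid = default_lambda_grid(),
                        maxit = 250, tol = 1e-6, fix_delta = NULL) {
  stopifnot(inherits(spec, "ModelSpec"), spec$model_type == "COZIGAM")
  pd <- prepare_fit_data(spec, data)
  y <- pd$y; offset <- pd$offset; data <- pd$data
  if (!any(y == 0)) {
    gspec <- spec; gspec$model_type <- "GAM"; gspec$zero_terms <- "intercept"
    g <- fit_gam(gspec, data, lambdas = lambdas, lambda_grid = lambda_grid)
    g$spec <- spec
    g$note <- "no zeros in response: COZIGAM reduces to a Poisson GAM with p = 1"
    return(g)
  }
  cdes <- build_component_design(data, spec$smooth_terms, spec$factor_terms)
  nlam <- length(cdes$smooth_ix)
  pos <- y > 0
  p_beta <- cdes$p
  free_delta <- is.null(fix_delta)
  # the linkage slope delta is a coefficient on log(mu); it receives the same
  # unit-information-scaled proper prior as smooth null-space coefficients so
  # that ZIGAM/COZIGAM evidence comparisons treat both zero models alike
  eta0 <- log(pmax(mean(y) / mean(exp(clip_lp(offset))), 1e-12)) + offset
  prec_delta <- if (free_delta) {
    max(NULLSPACE_PRIOR_WEIGHT * mean(eta0^2), 1e-8)
  } else 0

  theta_split <- function(th) {
    list(beta = th[seq_len(p_beta)], alpha = th[p_beta + 1],
         delta = if (free_delta) th[p_beta + 2] else fix_delta)
  }
  pen_obs_ll <- function(th, Sc) {
    sp <- theta_split(th)
    eta <- drop(cdes$X %*% sp$beta) + offset
    zeta <- sp$alpha + sp$delta * eta
    zip_obs_ll(y, eta, zeta) - 0.5 * sum(sp$beta * drop(Sc %*% sp$beta)) -
      0.5 * prec_delta * sp$delta^2
  }
  em_fit <- function(lam, init) {
    Sc <- component_penalty(cdes, lam)
    if (is.null(init)) {
      z <- ifelse(pos, 1, 0.3)
      cf <- fit_penalized_glm(y, cdes$X, Sc, offset, "poisson", weights = z)
      th <- c(cf$beta, stats::qlogis(min(max(mean(pos) + 0.05, 0.05), 0.95)),
              if (free_delta) 0)
    } else th <- init
    Q <- function(th, z) {
      sp <- theta_split(th)
      eta <- clip_lp(drop(cdes$X %*% sp$beta) + offset)
      zeta <- clip_lp(sp$alpha + sp$delta * eta)
      mu <- exp(eta)
      p <- pmin(pmax(stats::plogis(zeta), 1e-12), 1 - 1e-12)
      -(sum(z * (ifelse(y > 0, y * eta, 0) - mu - lgamma(y + 1))) +
          sum(z * log(p) + (1 - z) * log(1 - p)) -
          0.5 * sum(sp$beta * drop(Sc %*% sp$beta)) -
          0.5 * prec_delta * sp$delta^2)
    }
    Qgrad <- function(th, z) {
      sp <- theta_split(th)
      eta <- clip_lp(drop(cdes$X %*% sp$beta) + offset)
      zeta <- clip_lp(sp$alpha + sp$delta * eta)
      mu <- exp(eta)
      p <- pmin(pmax(stats::plogis(zeta), 1e-12), 1 - 1e-12)
      gb <- drop(crossprod(cdes$X, z * (y - mu) + sp$delta * (z - p))) -
        drop(Sc %*% sp$beta)
      ga <- sum(z - p)
      gd <- sum(eta * (z - p)) - prec_delta * sp$delta
      -c(gb, ga, if (free_delta) gd)
    }
    trace <- numeric(0)
    pll_old <- -Inf
    converged <- FALSE
    it <- 0
    z <- NULL
    while (it < maxit) {
      it <- it + 1
      sp <- theta_split(th)
      eta <- clip_lp(drop(cdes$X %*% sp$beta) + offset)
      zeta <- clip_lp(sp$alpha + sp$delta * eta)
      mu <- exp(eta)
      p <- pmin(pmax(stats::plogis(zeta), 1e-12), 1 - 1e-12)
      z <- ifelse(pos, 1, pmin(pmax(
        p * exp(-mu) / ((1 - p) + p * exp(-mu)), 1e-10), 1 - 1e-10))
      opt <- stats::optim(th, Q, Qgrad, z = z, method = "BFGS",
                          control = list(maxit = 60, reltol = 1e-11))
      # generalized EM: accept only if Q improved (optim minimizes)
      if (opt$value <= Q(th, z)) th <- opt$par
      pll <- pen_obs_ll(th, Sc)
      trace <- c(trace, pll)
      if (is.finite(pll_old) && abs(pll - pll_old) < tol * (abs(pll_old) + 1)) {
        converged <- TRUE
        break
      }
      pll_old <- pll
    }
    sp <- theta_split(th)
    eta <- clip_lp(drop(cdes$X %*% sp$beta) + offset)
    zeta <- clip_lp(sp$alpha + sp$delta * eta)
    list(theta = th, beta = sp$beta, alpha = sp$alpha, delta = sp$delta,
         Sc = Sc, mu = exp(eta), p = stats::plogis(zeta), z = z,
         eta = eta, zeta = zeta,
         ll_obs = zip_obs_ll(y, eta, zeta), pll_obs = trace[length(trace)],
         trace = trace, iterations = it, converged = converged)
  }
  evalf <- function(lam, state) {
    em <- em_fit(lam, if (!is.null(state)) state$theta else NULL)
    H <- pracma::hessian(function(th) -pen_obs_ll(th, em$Sc), em$theta)
    H <- (H + t(H)) / 2
    pc <- penalty_prior_const(cdes, lam) +
      if (free_delta) 0.5 * log(prec_delta / (2 * pi)) else 0
    logE <- laplace_logE_core(em$pll_obs, H, pc)
    list(logE = logE, state = list(theta = em$theta, em = em, H = H))
  }
  if (is.null(lambdas)) {
    sel <- select_lambdas(evalf, nlam, lambda_grid)
  } else {
    if (length(lambdas) != nlam) stop("need one lambda per smooth term")
    r <- evalf(lambdas, NULL)
    sel <- list(lambdas = lambdas, logE = r$logE, state = r$state)
  }
  em <- sel$state$em
  Vb <- tryCatch(chol2inv(chol(sel$state$H)), error = function(e)
    solve(sel$state$H + diag(mean(diag(sel$state$H)) * 1e-6,
                             nrow(sel$state$H))))
  # reporting edf for the count component from the weighted-Poisson
  # representation at convergence
  W <- em$z * em$mu
  XWX <- crossprod(cdes$X, cdes$X * W)
  Hc <- XWX + em$Sc
  Vc <- tryCatch(chol2inv(chol(Hc)), error = function(e)
    solve(Hc + diag(mean(diag(Hc)) * 1e-8, nrow(Hc))))
  edf_diag_c <- rowSums(Vc * t(XWX))
  l_sat <- mixture_sat_ll(y)
  l_null <- mixture_null_ll(y, offset)
  dev_expl <- if (l_sat - l_null > 1e-12) {
    1 - (l_sat - em$ll_obs) / (l_sat - l_null)
  } else 0
  assemble_fit(spec, data, length(y), cdes, NULL, em$beta, NULL,
               lambdas = named_lambdas(sel$lambdas, cdes, NULL),
               logE = sel$logE, ll_obs = em$ll_obs, Vb = Vb,
               edf_diag_c = edf_diag_c, edf_diag_z = NULL,
               dev_expl = dev_expl, em_iterations = em$iterations,
               converged = em$converged, em_trace = em$trace,
               mu = em$mu, p = em$p, offset = offset,
               alpha = em$alpha, delta = em$delta,
               extra_edf = 1 + as.numeric(free_delta))
}

#' Laplace-approximated log marginal likelihood of a fit
#'
#' Returns the model evidence computed at fit time: the penalized
#' log-likelihood at the posterior mode plus the Gaussian volume correction
#' \eqn{\frac{p}{2}\log 2\pi - \frac{1}{2}\log\lvert H\rvert} and the
#' normalizing constants of the smoothing-penalty priors on their range
#' spaces. Constant conventions are identical across GAM, ZIGAM and COZIGAM,
#' so logE values are directly comparable between model types.
#'
#' @param fit a `zs_fit`.
#' @return a single numeric logE value.
#' @export
log_marginal_likelihood <- function(fit) {
  stopifnot(inherits(fit, "zs_fit"))
  fit$logE
}

#' Per-term summary of a fitted abundance model
#'
#' Wald-type chi-square statistics per smooth term computed from the
#' coefficients and the posterior covariance, with the term's effective
#' degrees of freedom, plus model-level adjusted R-squared and proportion of
#' (mixture) deviance explained.
#'
#' @param fit a `zs_fit`.
#' @return data.frame with columns `term`, `edf`, `ref_df`, `chisq`, `p`;
#'   attributes `r2_adj` and `dev_expl`.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "zs_fit"))
  rows <- list()
  walk <- function(des, coefs, vcov_off, prefix) {
    if (is.null(des)) return()
    for (b in des$blocks) {
      if (b$type != "smooth") next
      idx <- b$idx
      bb <- coefs[idx]
      V <- fit$posterior_cov[vcov_off + idx, vcov_off + idx, drop = FALSE]
      eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-8
      Vinv <- eg$vectors[, pos, drop = FALSE] %*%
        (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
      chisq <- drop(t(bb) %*% Vinv %*% bb)
      edf <- fit$edf[[paste0(prefix, b$label)]]
      rows[[length(rows) + 1]] <<- data.frame(
        term = paste0(prefix, b$label), edf = edf, ref_df = edf,
        chisq = chisq,
        p = stats::pchisq(chisq, df = max(edf, 0.5), lower.tail = FALSE))
    }
  }
  walk(fit$count_design, fit$beta, 0L, "count:")
  if (!is.null(fit$zero_design)) {
    walk(fit$zero_design, fit$gamma, fit$count_design$p, "zero:")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), edf = numeric(), ref_df = numeric(),
               chisq = numeric(), p = numeric())
  attr(out, "r2_adj") <- fit$r2_adj
  attr(out, "dev_expl") <- fit$dev_expl
  out
}

#' Partial effect of one smooth term with a 95% credible band
#'
#' Centered partial effect of a smooth term on the link scale, with the
#' Bayesian posterior plus/minus 1.96 standard-error band (the band drawn in
#' effect-curve figures).
#'
#' @param fit a `zs_fit`.
#' @param term smooth label, e.g. `"s(temp)"` or just `"temp"`; prefix with
#'   `"zero:"` to address the zero-component copy of a mirrored smooth.
#' @param grid numeric vector (1-D) or data.frame/list of two vectors (2-D)
#'   of covariate values at which to evaluate the effect.
#' @return data.frame with the grid, `fit`, `se`, `lower`, `upper` and a
#'   logical `extrapolated` column.
#' @export
predict_partial <- function(fit, term, grid) {
  stopifnot(inherits(fit, "zs_fit"))
  component <- "count"
  if (grepl("^zero:", term)) {
    component <- "zero"
    term <- sub("^zero:", "", term)
  }
  term <- sub("^count:", "", term)
  des <- if (component == "count") fit$count_design else fit$zero_design
  if (is.null(des)) stop("model has no such component")
  coefs <- if (component == "count") fit$beta else fit$gamma
  off <- if (component == "count") 0L else fit$count_design$p
  hit <- NULL
  for (b in des$blocks) {
    if (b$type == "smooth" &&
        (b$label == term || b$label == sprintf("s(%s)", term))) hit <- b
  }
  if (is.null(hit)) stop(sprintf("term '%s' not found in the %s component",
                                 term, component))
  basis <- hit$basis
  vals <- evaluate_smooth(basis, coefs[hit$idx], grid)
  # rebuild prediction matrix for the SE band
  if (basis$dim == 1L) {
    xv <- as.numeric(if (is.list(grid)) grid[[1]] else grid)
    nd <- data.frame(xv); names(nd) <- basis$vars
    gout <- stats::setNames(data.frame(xv), basis$vars)
  } else {
    if (is.data.frame(grid)) grid <- as.list(grid)
    nd <- data.frame(as.numeric(grid[[1]]) / basis$scale[1],
                     as.numeric(grid[[2]]) / basis$scale[2])
    names(nd) <- basis$vars
    gout <- stats::setNames(data.frame(grid[[1]], grid[[2]]), basis$vars)
  }
  Xp <- mgcv::PredictMat(basis$sm, nd)
  V <- fit$posterior_cov[off + hit$idx, off + hit$idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((Xp %*% V) * Xp), 0))
  out <- cbind(gout, fit = as.numeric(vals), se = se,
               lower = as.numeric(vals) - 1.96 * se,
               upper = as.numeric(vals) + 1.96 * se,
               extrapolated = attr(vals, "extrapolated"))
  out
}
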