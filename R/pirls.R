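# Penalized IRLS for Poisson (log link) and binomial (logit link) components.
# This is the inner engine shared by every model type: it maximizes
#   l(beta) - 0.5 * beta' S beta
# for a fixed total penalty matrix S, with prior weights and an offset.
# Linear predictors are clipped at +/- 30 to guard against separation and
# all-zero responses.

LP_CLIP <- 30

clip_lp <- function(eta) pmin(pmax(eta, -LP_CLIP), LP_CLIP)

# Component log-likelihoods (fractional binomial responses permitted).
poisson_ll <- function(y, eta, w = 1) {
  mu <- exp(clip_lp(eta))
  sum(w * (ifelse(y > 0, y * clip_lp(eta), 0) - mu - lgamma(y + 1)))
}

binomial_ll <- function(y, eta, w = 1) {
  eta <- clip_lp(eta)
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# Solve (A + ridge) b = r with Cholesky, adding jitter if A is numerically
# singular (near-unidentifiable smooths at extreme lambda).
chol_solve <- function(A, r) {
  d <- mean(diag(A))
  for (ridge in c(0, d * 10^seq(-10, -4, by = 2))) {
    R <- tryCatch(chol(A + diag(ridge, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(backsolve(R, forwardsolve(t(R), r)))
  }
  qr.solve(A + diag(d * 1e-4, nrow(A)), r)
}

#' Penalized GLM fit at fixed smoothing parameters
#'
#' Penalized iteratively reweighted least squares (P-IRLS) for a single model
#' component. Maximizes the penalized log-likelihood
#' \eqn{l(\beta) - \frac{1}{2}\beta^\top S \beta} for the given total penalty
#' matrix, returning coefficients, the effective degrees of freedom (trace of
#' the influence matrix), and the coefficient precision/covariance used by the
#' Laplace evidence.
#'
#' @param y response vector (counts for `poisson`; values in \[0, 1\],
#'   fractional allowed, for `binomial`).
#' @param X model matrix.
#' @param S total penalty matrix (p x p), e.g. from [component_penalty()].
#' @param offset linear-predictor offset (default 0).
#' @param family `"poisson"` (log link) or `"binomial"` (logit link).
#' @param weights prior weights (EM responsibilities in the mixture M-step).
#' @param beta_init optional warm start.
#' @param maxit IRLS iteration cap; exceeding it raises a convergence error of
#'   class `pirls_convergence_error` carrying the last iterate in
#'   `$last_fit`.
#' @param tol relative penalized log-likelihood convergence tolerance.
#' @return list with `beta`, `eta`, `mu`, `ll` (unpenalized), `pll`
#'   (penalized), `edf` (total), `edf_diag` (per-coefficient), `H`
#'   (penalized information X'WX + S), `Vb` (its inverse), `iterations`,
#'   `converged`.
#' @export
fit_penalized_glm <- function(y, X, S = matrix(0, ncol(X), ncol(X)),
                              offset = 0, family = c("poisson", "binomial"),
                              weights = NULL, beta_init = NULL,
                              maxit = 200, tol = 1e-10) {
  family <- match.arg(family)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design rows must equal length(y)")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(offset) == 1) offset <- rep(offset, n)
  beta <- if (is.null(beta_init)) rep(0, p) else beta_init
  if (is.null(beta_init) && family == "poisson") {
    ybar <- sum(w * y) / max(sum(w * exp(clip_lp(offset))), 1e-12)
    beta[1] <- clip_lp(log(max(ybar, 1e-12)))
  }
  llfun <- if (family == "poisson") poisson_ll else binomial_ll
  pll <- function(b) {
    llfun(y, drop(X %*% b) + offset, w) - 0.5 * sum(b * drop(S %*% b))
  }
  obj <- pll(beta)
  converged <- FALSE
  it <- 0
  W <- NULL
  while (it < maxit) {
    it <- it + 1
    eta <- clip_lp(drop(X %*% beta) + offset)
    if (family == "poisson") {
      mu <- exp(eta)
      W <- w * mu
      z <- (eta - offset) + (y - mu) / pmax(mu, 1e-10)
    } else {
      mu <- stats::plogis(eta)
      v <- pmax(mu * (1 - mu), 1e-10)
      W <- w * v
      z <- (eta - offset) + (y - mu) / v
    }
    A <- crossprod(X, X * W) + S
    b_new <- drop(chol_solve(A, crossprod(X, W * z)))
    obj_new <- pll(b_new)
    dir <- b_new - beta
    step <- 1
    while (!is.finite(obj_new) || obj_new < obj - 1e-12) {
      step <- step / 2
      if (step < 1e-8) { b_new <- beta; obj_new <- obj; break }
      b_new <- beta + step * dir
      obj_new <- pll(b_new)
    }
    done <- abs(obj_new - obj) < tol * (abs(obj) + 1)
    beta <- b_new
    obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  eta <- clip_lp(drop(X %*% beta) + offset)
  mu <- if (family == "poisson") exp(eta) else stats::plogis(eta)
  W <- if (family == "poisson") w * mu else w * pmax(mu * (1 - mu), 1e-10)
  XWX <- crossprod(X, X * W)
  H <- XWX + S
  Vb <- tryCatch(chol2inv(chol(H)), error = function(e)
    solve(H + diag(mean(diag(H)) * 1e-8, p)))
  Fmat_diag <- rowSums(Vb * t(XWX))  # diag of Vb %*% XWX
  out <- list(beta = beta, eta = eta, mu = mu,
              ll = llfun(y, eta, w), pll = obj,
              edf = sum(Fmat_diag), edf_diag = Fmat_diag,
              H = H, XWX = XWX, Vb = Vb, W = W,
              iterations = it, converged = converged)
  if (!converged) {
    cond <- structure(class = c("pirls_convergence_error", "error", "condition"),
                      list(message = sprintf(
                        "P-IRLS did not converge in %d iterations", maxit),
                        call = sys.call(-1), last_fit = out))
    stop(cond)
  }
  out
}
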