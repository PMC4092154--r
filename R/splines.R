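#' Low-rank thin-plate regression spline bases
#'
#' Builds the penalized smoothing bases used by the abundance models: low-rank
#' eigen-truncated thin-plate regression splines (TPRS) with a wiggliness
#' penalty whose null space contains polynomials (constant + linear terms).
#' The sum-to-zero identifiability constraint is absorbed into the basis by
#' reparameterization, so the returned design columns are directly usable next
#' to an intercept.
#'
#' @param x numeric vector of covariate values (no missing values).
#' @param k basis dimension before constraint absorption; must be >= 3 and not
#'   exceed the number of distinct values of `x`.
#' @param label optional term label; defaults to `s(<name>)`.
#' @return an object of class `SmoothBasis` with elements
#'   \describe{
#'     \item{vars}{covariate name(s)}
#'     \item{k}{requested basis dimension}
#'     \item{X}{n x (k-1) constrained design block}
#'     \item{S}{constrained penalty matrix (symmetric PSD)}
#'     \item{null_space_dim}{penalty null-space dimension of the unconstrained
#'       basis (2 in 1-D: constant + linear; 3 in 2-D)}
#'     \item{xrange}{per-variable training range, used to flag extrapolation}
#'   }
#' @export
build_tprs_basis <- function(x, k = 10, label = NULL) {
  if (k < 3) stop("basis dimension k must be >= 3")
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values in smooth covariate")
  if (length(unique(x)) < k) {
    stop(sprintf("basis dimension error: k = %d but only %d distinct values",
                 k, length(unique(x))))
  }
  nm <- if (is.null(label)) "x" else label
  dat <- data.frame(x = x)
  names(dat) <- nm
  sm <- mgcv::smoothCon(eval(call("s", as.name(nm), bs = "tp", k = k)),
                        data = dat, knots = NULL, absorb.cons = TRUE)[[1]]
  out <- list(
    vars = nm,
    k = k,
    X = sm$X,
    S = sm$S[[1]],
    null_space_dim = 2L,
    sm = sm,
    xrange = list(range(x)),
    dim = 1L
  )
  names(out$xrange) <- nm
  class(out) <- "SmoothBasis"
  out
}

#' Isotropic 2-D thin-plate regression spline basis
#'
#' Single bivariate smooth on coordinates standardized to unit variance, so
#' that covariates on very different scales (e.g. year and month) share one
#' isotropic wiggliness penalty. Penalty null space spans \{1, x1, x2\}.
#'
#' @param x1,x2 numeric covariate vectors of equal length.
#' @param k basis dimension (>= 4).
#' @param labels character vector of length 2 naming the covariates.
#' @return a `SmoothBasis` (see [build_tprs_basis()]); `scale` holds the
#'   standardization applied to each coordinate.
#' @export
build_tprs_basis_2d <- function(x1, x2, k = 25, labels = c("x1", "x2")) {
  if (k < 4) stop("basis dimension k must be >= 4 for a 2-D smooth")
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (anyNA(x1) || anyNA(x2)) stop("missing values in smooth covariates")
  nd <- nrow(unique(cbind(x1, x2)))
  if (nd < k) {
    stop(sprintf("basis dimension error: k = %d but only %d distinct points", k, nd))
  }
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  if (s1 == 0 || s2 == 0) {
    warning("degenerate 2-D smooth input: a coordinate is constant")
    s1 <- max(s1, 1); s2 <- max(s2, 1)
  }
  dat <- data.frame(x1 / s1, x2 / s2)
  names(dat) <- labels
  sm <- mgcv::smoothCon(eval(call("s", as.name(labels[1]), as.name(labels[2]),
                                  bs = "tp", k = k)),
                        data = dat, knots = NULL, absorb.cons = TRUE)[[1]]
  out <- list(
    vars = labels,
    k = k,
    X = sm$X,
    S = sm$S[[1]],
    null_space_dim = 3L,
    sm = sm,
    xrange = list(range(x1), range(x2)),
    scale = c(s1, s2),
    dim = 2L
  )
  names(out$xrange) <- labels
  class(out) <- "SmoothBasis"
  out
}

#' Evaluate a fitted smooth at new covariate values
#'
#' Linear in the coefficients; at the training covariates it reproduces
#' `basis$X %*% coefs`. Values requested outside the training range are
#' returned but flagged.
#'
#' @param basis a `SmoothBasis`.
#' @param coefs coefficient vector of length `ncol(basis$X)`.
#' @param xnew numeric vector (1-D) or list/data.frame of two vectors (2-D).
#' @return numeric vector of smooth values with attribute `extrapolated`, a
#'   logical vector marking points outside the training range.
#' @export
evaluate_smooth <- function(basis, coefs, xnew) {
  stopifnot(inherits(basis, "SmoothBasis"))
  if (length(coefs) != ncol(basis$X)) {
    stop(sprintf("coefs must have length %d", ncol(basis$X)))
  }
  if (basis$dim == 1L) {
    xv <- as.numeric(if (is.list(xnew)) xnew[[1]] else xnew)
    nd <- data.frame(xv)
    names(nd) <- basis$vars
    extrap <- xv < basis$xrange[[1]][1] | xv > basis$xrange[[1]][2]
  } else {
    if (is.data.frame(xnew)) xnew <- as.list(xnew)
    if (!is.list(xnew) || length(xnew) < 2) {
      stop("2-D smooth evaluation needs two covariate vectors")
    }
    v1 <- as.numeric(xnew[[1]]); v2 <- as.numeric(xnew[[2]])
    nd <- data.frame(v1 / basis$scale[1], v2 / basis$scale[2])
    names(nd) <- basis$vars
    extrap <- v1 < basis$xrange[[1]][1] | v1 > basis$xrange[[1]][2] |
      v2 < basis$xrange[[2]][1] | v2 > basis$xrange[[2]][2]
  }
  Xp <- mgcv::PredictMat(basis$sm, nd)
  out <- drop(Xp %*% coefs)
  attr(out, "extrapolated") <- extrap
  out
}

#' @export
print.SmoothBasis <- function(x, ...) {
  cat(sprintf("TPRS basis s(%s): k = %d, rank(S) = %d, null space = %d\n",
              paste(x$vars, collapse = ","), x$k,
              qr(x$S)$rank, x$null_space_dim))
  invisible(x)
}
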