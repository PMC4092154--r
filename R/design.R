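#' Declare an abundance model structure
#'
#' A `ModelSpec` describes a catch-rate model declaratively: the model family
#' (`GAM` = Poisson GAM, `ZIGAM` = zero-inflated GAM fitted by EM, `COZIGAM` =
#' constrained ZIGAM with logit(p) = alpha + delta * log(mu)), the response
#' species column, the smooth and factor terms of the count component, the
#' effort column used as a log offset, and the structure of the zero
#' (regular-state probability) component.
#'
#' @param model_type one of `"GAM"`, `"ZIGAM"`, `"COZIGAM"`.
#' @param response name of the count column to model.
#' @param smooth_terms list of smooth terms created by [sm()].
#' @param factor_terms character vector of factor covariates (reference level
#'   is `"BV"` for `site` when present, otherwise the first level).
#' @param offset name of the strictly positive effort column; its log is added
#'   to the count linear predictor.
#' @param zero_terms structure of the zero component for ZIGAM: `"mirror"`
#'   (default; same smooth and factor terms as the count component),
#'   `"intercept"` (constant regular-state probability), or a list with
#'   elements `smooth_terms` and `factor_terms`. Ignored for GAM; COZIGAM
#'   derives its zero component from the count component.
#' @return an object of class `ModelSpec`.
#' @export
model_spec <- function(model_type = c("ZIGAM", "GAM", "COZIGAM"), response,
                       smooth_terms = list(), factor_terms = character(),
                       offset = "effort_hooks", zero_terms = "mirror") {
  model_type <- match.arg(model_type)
  if (length(smooth_terms) && !is.null(smooth_terms$vars)) {
    smooth_terms <- list(smooth_terms)  # single bare term
  }
  vars <- unlist(lapply(smooth_terms, `[[`, "vars"))
  if (anyDuplicated(vars)) stop("a covariate appears in smooth_terms twice")
  structure(list(model_type = model_type, response = response,
                 smooth_terms = smooth_terms, factor_terms = factor_terms,
                 offset = offset, zero_terms = zero_terms),
            class = "ModelSpec")
}

#' Smooth term constructor
#'
#' @param vars one covariate name (1-D TPRS) or two (isotropic 2-D TPRS on
#'   standardized coordinates).
#' @param k basis dimension; defaults to 10 (1-D) or 25 (2-D).
#' @return a smooth-term descriptor for [model_spec()].
#' @export
sm <- function(vars, k = if (length(vars) == 2) 25 else 10) {
  stopifnot(length(vars) %in% 1:2)
  list(vars = vars, k = k)
}

#' @export
print.ModelSpec <- function(x, ...) {
  smo <- vapply(x$smooth_terms, function(s)
    sprintf("s(%s,k=%d)", paste(s$vars, collapse = ","), s$k), "")
  cat(sprintf("%s: %s ~ %s + offset(log(%s))\n", x$model_type, x$response,
              paste(c("1", x$factor_terms, smo), collapse = " + "), x$offset))
  invisible(x)
}

# Build the model-matrix for one model component (count or zero).
# Returns X plus block metadata: index ranges, penalty matrices with their
# ranks and positive log-determinants (needed by the Laplace evidence).
build_component_design <- function(data, smooth_terms = list(),
                                   factor_terms = character()) {
  n <- nrow(data)
  Xl <- list(matrix(1, n, 1))
  colnames(Xl[[1]]) <- "(Intercept)"
  blocks <- list(list(label = "(Intercept)", type = "intercept", ncol = 1L))
  for (nm in factor_terms) {
    f <- data[[nm]]
    if (is.null(f)) stop(sprintf("factor covariate '%s' not found", nm))
    lev <- if (is.factor(f)) levels(f) else sort(unique(as.character(f)))
    if (nm == "site" && "BV" %in% lev) lev <- c("BV", setdiff(lev, "BV"))
    f <- factor(as.character(f), levels = lev)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(nm, lev[-1])
    Xl[[length(Xl) + 1]] <- mm
    blocks[[length(blocks) + 1]] <- list(label = nm, type = "factor",
                                         ncol = ncol(mm), levels = lev)
  }
  for (st in smooth_terms) {
    v <- st$vars
    lab <- sprintf("s(%s)", paste(v, collapse = ","))
    if (length(v) == 1) {
      b <- build_tprs_basis(data[[v]], k = st$k, label = v)
    } else {
      b <- build_tprs_basis_2d(data[[v[1]]], data[[v[2]]], k = st$k, labels = v)
    }
    ev <- eigen(b$S, symmetric = TRUE, only.values = TRUE)$values
    keep <- ev > max(ev) * 1e-10
    Xs <- b$X
    colnames(Xs) <- paste0(lab, ".", seq_len(ncol(Xs)))
    # proper (weak, unit-information-scaled) Gaussian prior on the penalty
    # null-space columns: keeps the Laplace evidence well defined when
    # models with different smooth terms are compared
    nullprec <- rep(0, ncol(Xs))
    nullcols <- which(abs(diag(b$S)) <= max(abs(diag(b$S))) * 1e-10)
    nullprec[nullcols] <- pmax(
      NULLSPACE_PRIOR_WEIGHT * colSums(Xs[, nullcols, drop = FALSE]^2) / n,
      1e-8)
    Xl[[length(Xl) + 1]] <- Xs
    blocks[[length(blocks) + 1]] <- list(label = lab, type = "smooth",
                                         ncol = ncol(Xs), basis = b,
                                         S = b$S, rank = sum(keep),
                                         logdetS = sum(log(ev[keep])),
                                         nullprec = nullprec)
  }
  X <- do.call(cbind, Xl)
  p0 <- 0L
  for (i in seq_along(blocks)) {
    blocks[[i]]$idx <- p0 + seq_len(blocks[[i]]$ncol)
    p0 <- p0 + blocks[[i]]$ncol
  }
  list(X = X, blocks = blocks, p = ncol(X),
       smooth_ix = which(vapply(blocks, `[[`, "", "type") == "smooth"))
}

# Relative weight of the proper Gaussian prior placed on smooth null-space
# coefficients (precision = weight * mean squared column scale); weak enough
# to leave fits essentially unshrunk, proper enough to make evidence
# comparisons across different smooth sets well defined.
NULLSPACE_PRIOR_WEIGHT <- 0.01

# Total penalty matrix for a component at smoothing parameters `lambdas`
# (one per smooth block, in block order), including the fixed null-space
# prior precisions.
component_penalty <- function(design, lambdas) {
  S <- matrix(0, design$p, design$p)
  for (j in seq_along(design$smooth_ix)) {
    b <- design$blocks[[design$smooth_ix[j]]]
    S[b$idx, b$idx] <- S[b$idx, b$idx] + lambdas[j] * b$S + diag(b$nullprec)
  }
  S
}

# Laplace-prior normalizing constants for a component's penalties:
# sum_j 0.5 * (rank_j * log(lambda_j) + logdet+ S_j - rank_j * log(2*pi))
# plus the proper null-space prior constants.
penalty_prior_const <- function(design, lambdas) {
  out <- 0
  for (j in seq_along(design$smooth_ix)) {
    b <- design$blocks[[design$smooth_ix[j]]]
    np <- b$nullprec[b$nullprec > 0]
    out <- out + 0.5 * (b$rank * log(lambdas[j]) + b$logdetS -
                          b$rank * log(2 * pi)) +
      0.5 * sum(log(np / (2 * pi)))
  }
  out
}
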