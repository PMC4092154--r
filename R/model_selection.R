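# Model-selection workflow: per-predictor basis-dimension optimization,
# GAM/ZIGAM/COZIGAM adjudication, spatiotemporal (SPT1/SPT2) model
# construction, and forward stepwise environmental-model selection under the
# screening exclusion constraints. All comparisons are on the Laplace
# evidence logE.

#' Fit a model from its declarative specification
#'
#' Dispatches to [fit_gam()], [fit_zigam()] or [fit_cozigam()] according to
#' `spec$model_type`.
#'
#' @param spec a [model_spec()].
#' @param data cruise-level data.frame.
#' @param ... passed to the fitter (e.g. `lambdas`, `lambda_grid`).
#' @return a `zs_fit`.
#' @export
fit_model <- function(spec, data, ...) {
  fitter <- switch(spec$model_type, GAM = fit_gam, ZIGAM = fit_zigam,
                   COZIGAM = fit_cozigam)
  fitter(spec, data, ...)
}

#' Optimize the basis dimension of a univariate smooth
#'
#' Fits univariate ZIGAMs of one species against one predictor over a grid of
#' basis dimensions and returns the k maximizing logE; ties (within 1e-6) are
#' broken toward the smaller k (parsimony).
#'
#' @param data cruise-level data.frame.
#' @param species response count column.
#' @param predictor covariate name.
#' @param k_grid candidate basis dimensions (each >= 3).
#' @param zero_terms zero-component structure (see [model_spec()]).
#' @param ... passed to [fit_zigam()].
#' @return chosen k, with attribute `logE` (named vector over the grid,
#'   `NA` for failed fits).
#' @export
optimize_basis_dim <- function(data, species, predictor,
                               k_grid = c(4, 6, 8, 10, 12),
                               zero_terms = "mirror", ...) {
  stopifnot(length(k_grid) >= 1, all(k_grid >= 3))
  k_grid <- sort(unique(k_grid))
  logE <- stats::setNames(rep(NA_real_, length(k_grid)), k_grid)
  errs <- character(0)
  for (i in seq_along(k_grid)) {
    sp <- model_spec("ZIGAM", species, list(sm(predictor, k = k_grid[i])),
                     zero_terms = zero_terms)
    ft <- tryCatch(suppressWarnings(fit_zigam(sp, data, ...)),
                   error = function(e) e)
    if (inherits(ft, "error")) {
      errs <- c(errs, sprintf("k=%d: %s", k_grid[i], conditionMessage(ft)))
    } else {
      logE[i] <- ft$logE
    }
  }
  if (all(is.na(logE))) {
    stop(sprintf("selection error: all basis dimensions failed (%s)",
                 paste(errs, collapse = "; ")))
  }
  best <- which(logE >= max(logE, na.rm = TRUE) - 1e-6)[1]
  structure(k_grid[best], logE = logE)
}

#' Adjudicate the model type by univariate evidence comparisons
#'
#' Fits GAM, ZIGAM and COZIGAM univariately for each predictor of one or
#' more species and records the Laplace evidence (a failed or non-converged
#' fit is recorded as `NA`, never raised). The chosen type is the one with
#' the highest logE for the largest number of (species, predictor) cells;
#' ties go to ZIGAM.
#'
#' @param data cruise-level data.frame.
#' @param species character vector of response columns.
#' @param predictors character vector of covariates.
#' @param k basis dimension of the univariate smooths.
#' @param ... passed to the fitters.
#' @return list with `table` (one row per species x predictor with columns
#'   `GAM`, `ZIGAM`, `COZIGAM`) and `chosen_type`.
#' @export
adjudicate_model_type <- function(data, species, predictors, k = 6, ...) {
  stopifnot(length(predictors) >= 1)
  rows <- list()
  for (spn in species) {
    for (pr in predictors) {
      le <- c(GAM = NA_real_, ZIGAM = NA_real_, COZIGAM = NA_real_)
      for (ty in names(le)) {
        sp <- model_spec(ty, spn, list(sm(pr, k = k)))
        ft <- tryCatch(suppressWarnings(fit_model(sp, data, ...)),
                       error = function(e) NULL)
        if (!is.null(ft) && isTRUE(ft$converged)) le[ty] <- ft$logE
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = spn, predictor = pr, GAM = le["GAM"], ZIGAM = le["ZIGAM"],
        COZIGAM = le["COZIGAM"], row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  wins <- c(GAM = 0, ZIGAM = 0, COZIGAM = 0)
  for (i in seq_len(nrow(tab))) {
    le <- unlist(tab[i, c("GAM", "ZIGAM", "COZIGAM")])
    if (all(is.na(le))) next
    wins[which.max(le)] <- wins[which.max(le)] + 1
  }
  best <- max(wins)
  chosen <- if (wins["ZIGAM"] == best) "ZIGAM" else names(wins)[which.max(wins)]
  list(table = tab, chosen_type = chosen)
}

#' Build the two spatiotemporal model specifications
#'
#' SPT1 treats year and month as independent smooth functions next to the
#' site factor; SPT2 links year and month through a single shared (isotropic,
#' standardized-coordinate) bivariate smooth. Both carry the log-effort
#' offset and reference site BV.
#'
#' @param species response count column.
#' @param sites site factor levels present in the data (>= 2).
#' @param model_type model family for both specs.
#' @param k_year,k_month,k_2d basis dimensions.
#' @param zero_terms zero-component structure (ZIGAM only).
#' @return list with elements `SPT1` and `SPT2` ([model_spec()] objects).
#' @export
build_spt_specs <- function(species, sites = c("BV", "PA", "CS"),
                            model_type = "ZIGAM", k_year = 8, k_month = 8,
                            k_2d = 20, zero_terms = "intercept") {
  if (length(sites) < 2) stop("need at least 2 site levels")
  list(
    SPT1 = model_spec(model_type, species,
                      list(sm("year", k = k_year), sm("month", k = k_month)),
                      factor_terms = "site", zero_terms = zero_terms),
    SPT2 = model_spec(model_type, species,
                      list(sm(c("year", "month"), k = k_2d)),
                      factor_terms = "site", zero_terms = zero_terms)
  )
}

pair_excluded <- function(a, b, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(FALSE)
  any((exclusions[, 1] == a & exclusions[, 2] == b) |
        (exclusions[, 1] == b & exclusions[, 2] == a))
}

#' Forward stepwise construction of the environmental model
#'
#' Starting from the site factor (optional) plus the log-effort offset, each
#' step adds the candidate smooth with the largest Laplace evidence among
#' candidates not excluded (by the correlation screen) against any covariate
#' already included; the search stops at the first step with no evidence
#' improvement. The trace records every evaluation.
#'
#' @param data cruise-level data.frame.
#' @param species response count column.
#' @param candidates candidate covariate names (must not contain year/month,
#'   which belong to the spatiotemporal models).
#' @param exclusions 2-column matrix/data.frame of excluded pairs (from
#'   [screen_covariates()]).
#' @param site_factor include `site` as a factor (kept at every step).
#' @param model_type model family.
#' @param k basis dimension of candidate smooths.
#' @param zero_terms zero-component structure (ZIGAM only).
#' @param ... passed to the fitters.
#' @return list of class `SelectionTrace`: `steps` (data.frame of every
#'   evaluation: step, candidate, logE, accepted), `final_spec`, `final_fit`,
#'   `included`.
#' @export
forward_stepwise_env <- function(data, species, candidates,
                                 exclusions = NULL, site_factor = TRUE,
                                 model_type = "ZIGAM", k = 6,
                                 zero_terms = "intercept", ...) {
  if (any(c("year", "month") %in% candidates)) {
    stop("year/month belong to the SPT models, not the ENV candidates")
  }
  if (!is.null(exclusions)) exclusions <- as.matrix(exclusions)
  fac <- if (site_factor) "site" else character(0)
  mk_spec <- function(vars) {
    model_spec(model_type, species, lapply(vars, function(v) sm(v, k = k)),
               factor_terms = fac, zero_terms = zero_terms)
  }
  fit1 <- function(spec) suppressWarnings(fit_model(spec, data, ...))
  included <- character(0)
  cur_spec <- mk_spec(included)
  cur_fit <- fit1(cur_spec)
  cur_logE <- cur_fit$logE
  steps <- list()
  step_no <- 0
  repeat {
    step_no <- step_no + 1
    open <- setdiff(candidates, included)
    open <- open[!vapply(open, function(cnd)
      any(vapply(included, pair_excluded, TRUE, b = cnd,
                 exclusions = exclusions)), TRUE)]
    if (!length(open)) break
    evals <- lapply(open, function(cnd) {
      ft <- tryCatch(fit1(mk_spec(c(included, cnd))),
                     error = function(e) NULL)
      list(candidate = cnd, logE = if (is.null(ft)) NA_real_ else ft$logE,
           fit = ft)
    })
    les <- vapply(evals, function(e) ifelse(is.na(e$logE), -Inf, e$logE), 1)
    best <- which.max(les)
    improved <- is.finite(les[best]) && les[best] > cur_logE
    for (i in seq_along(evals)) {
      steps[[length(steps) + 1]] <- data.frame(
        step = step_no, candidate = evals[[i]]$candidate,
        logE = evals[[i]]$logE,
        accepted = improved && i == best, stringsAsFactors = FALSE)
    }
    if (!improved) break
    included <- c(included, evals[[best]]$candidate)
    cur_fit <- evals[[best]]$fit
    cur_spec <- mk_spec(included)
    cur_logE <- les[best]
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), candidate = character(), logE = numeric(),
               accepted = logical())
  rownames(steps) <- NULL
  structure(list(steps = steps, final_spec = cur_spec, final_fit = cur_fit,
                 included = included, base_logE = cur_logE),
            class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat(sprintf("Forward stepwise ENV selection: %d evaluation(s), final terms: %s\n",
              nrow(x$steps),
              if (length(x$included)) paste(x$included, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Wald tests of site effects against the reference site
#'
#' @param fit a `zs_fit` whose count component contains a site factor.
#' @return data.frame with one row per non-reference level: `level`,
#'   `estimate`, `se`, `Z`, `p` (two-sided); the reference level is omitted.
#' @export
site_effect_tests <- function(fit) {
  stopifnot(inherits(fit, "zs_fit"))
  des <- fit$count_design
  hit <- NULL
  for (b in des$blocks) if (b$type == "factor") hit <- b
  if (is.null(hit)) stop("lookup error: model has no factor term")
  est <- fit$beta[hit$idx]
  se <- sqrt(pmax(diag(fit$posterior_cov)[hit$idx], 0))
  Z <- est / se
  data.frame(level = hit$levels[-1], estimate = est, se = se, Z = Z,
             p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}
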