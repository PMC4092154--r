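# Covariate correlation screening.
#
# Candidate predictors are screened pairwise before modeling: Pearson's r
# with a Student-t test on n - 2 df and a Fisher-Z 95% confidence interval,
# Spearman's rank correlation s, and a three-criterion rule flagging
# "problematic" pairs that must not enter the same model.

#' Pearson correlation with t-test and Fisher-Z confidence interval
#'
#' @param x,y numeric vectors; pairs with a missing member are dropped
#'   (pairwise-complete).
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame: `n`, `r`, `t_stat`, `df` (= n - 2), `p`
#'   (two-sided), `ci_low`, `ci_high`.
#' @export
pearson_with_fisher_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("sample-size error: need at least 4 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  z <- atanh(r)
  hw <- stats::qnorm((1 + conf) / 2) / sqrt(n - 3)
  data.frame(n = n, r = r, t_stat = t_stat, df = df, p = p,
             ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Invert the correlation t-statistic
#'
#' Recovers `r` from its Student-t statistic: `r = t / sqrt(t^2 + df)`,
#' sign-preserving.
#'
#' @param t_stat t statistic.
#' @param df degrees of freedom (n - 2, must be >= 2).
#' @return the correlation coefficient.
#' @export
t_to_r <- function(t_stat, df) {
  stopifnot(df >= 2)
  t_stat / sqrt(t_stat^2 + df)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' Pearson correlation of mid-ranks; ties receive average ranks.
#'
#' @param x,y numeric vectors (pairwise-complete observations used).
#' @return Spearman's s.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("sample-size error: need at least 4 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: constant input")
  }
  stats::cor(rx, ry)
}

#' Three-criterion problematic-pair rule
#'
#' A covariate pair is flagged when all of: (i) the null hypothesis rho = 0
#' is rejected (p < 0.05); (ii) the highest absolute confidence-interval
#' endpoint for rho is >= the threshold; and (iii) either |s| or the lowest
#' absolute confidence-interval endpoint is >= the threshold. Sign-agnostic.
#'
#' @param res one-row data.frame (or list) with `p`, `ci_low`, `ci_high`, `s`.
#' @param threshold correlation magnitude regarded as non-small (default 0.3).
#' @return logical flag.
#' @export
is_problematic <- function(res, threshold = 0.3) {
  a <- abs(res$ci_low); b <- abs(res$ci_high)
  hi <- pmax(a, b); lo <- pmin(a, b)
  unname(res$p < 0.05 & hi >= threshold & (abs(res$s) >= threshold | lo >= threshold))
}

#' Screen a covariate table for problematic correlations
#'
#' Evaluates every unordered covariate pair on pairwise-complete rows:
#' Pearson r with t-test and Fisher-Z interval, Spearman s, and the
#' three-criterion flag. Pairs are ordered lexicographically for
#' deterministic output.
#'
#' @param table cruise-level data.frame.
#' @param covariates covariate column names (>= 2).
#' @param threshold see [is_problematic()].
#' @return data.frame with one row per pair (`cov1`, `cov2`, `n`, `t_stat`,
#'   `df`, `p`, `ci_low`, `ci_high`, `r`, `s`, `problematic`); attribute
#'   `exclusions` holds the flagged pairs as a 2-column matrix.
#' @export
screen_covariates <- function(table, covariates, threshold = 0.3) {
  covariates <- sort(unique(covariates))
  if (length(covariates) < 2) {
    out <- empty_screen()
    attr(out, "exclusions") <- matrix(character(0), ncol = 2)
    return(out)
  }
  rows <- list()
  for (i in seq_along(covariates)[-length(covariates)]) {
    for (j in seq((i + 1), length(covariates))) {
      c1 <- covariates[i]; c2 <- covariates[j]
      pc <- pearson_with_fisher_ci(table[[c1]], table[[c2]])
      s <- spearman_rho(table[[c1]], table[[c2]])
      row <- data.frame(cov1 = c1, cov2 = c2, n = pc$n, t_stat = pc$t_stat,
                        df = pc$df, p = pc$p, ci_low = pc$ci_low,
                        ci_high = pc$ci_high, r = pc$r, s = s,
                        stringsAsFactors = FALSE)
      row$problematic <- is_problematic(row, threshold)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <-
    as.matrix(out[out$problematic, c("cov1", "cov2"), drop = FALSE])
  out
}

empty_screen <- function() {
  data.frame(cov1 = character(), cov2 = character(), n = integer(),
             t_stat = numeric(), df = integer(), p = numeric(),
             ci_low = numeric(), ci_high = numeric(), r = numeric(),
             s = numeric(), problematic = logical())
}

#' Apply the problematic-pair rule to precomputed correlation statistics
#'
#' For re-screening published correlation summaries (p-values, Fisher-Z
#' interval endpoints and Spearman s) without the raw data.
#'
#' @param stats data.frame with columns `cov1`, `cov2`, `p` (numeric; strings
#'   like `"<0.001"` are accepted and read as their bound), `ci_low`,
#'   `ci_high`, `s`.
#' @param threshold see [is_problematic()].
#' @return the input with a logical `problematic` column appended; attribute
#'   `exclusions` as in [screen_covariates()].
#' @export
screen_from_stats <- function(stats, threshold = 0.3) {
  p <- stats$p
  if (!is.numeric(p)) {
    p <- vapply(as.character(p), function(v) {
      if (grepl("^<", v)) as.numeric(sub("^<", "", v)) - 1e-12
      else as.numeric(v)
    }, 1)
  }
  out <- stats
  out$problematic <- is_problematic(
    list(p = p, ci_low = stats$ci_low, ci_high = stats$ci_high, s = stats$s),
    threshold)
  attr(out, "exclusions") <-
    as.matrix(out[out$problematic, c("cov1", "cov2"), drop = FALSE])
  out
}

#' Published pairwise correlation summaries of the Recife survey covariates
#'
#' The 23 pairwise correlation summaries reported for the survey's
#' environmental covariates (t statistic, degrees of freedom, p-value,
#' Fisher-Z 95% interval, Pearson r, Spearman s), usable as input to
#' [screen_from_stats()].
#'
#' @return data.frame with columns `cov1`, `cov2`, `t_stat`, `df`, `p`
#'   (character; `"<0.001"` preserved), `ci_low`, `ci_high`, `r`, `s`.
#' @export
recife_correlation_table <- function() {
  path <- system.file("extdata", "recife_correlations.csv",
                      package = "zigamsurvey", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    cov1 = "character", cov2 = "character", t_stat = "numeric",
    df = "integer", p = "character", ci_low = "numeric",
    ci_high = "numeric", r = "numeric", s = "numeric"))
}
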