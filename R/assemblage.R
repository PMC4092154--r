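# Assemblage composition statistics: sex ratios, sex-by-period shifts, and
# total-length comparisons between sexes, years and quarters.

#' Chi-square goodness-of-fit test against a 1:1 sex ratio
#'
#' Uncorrected (no Yates continuity correction) chi-square with expected
#' counts (m + f) / 2 in each cell, df = 1; equivalently
#' \eqn{\chi^2 = (m - f)^2 / (m + f)}.
#'
#' @param males,females non-negative integer counts (at least one positive).
#' @return data.frame with `statistic`, `df`, `p`, `method`.
#' @export
sex_ratio_gof <- function(males, females) {
  if (males + females < 1) stop("undefined test: no sexed individuals")
  ht <- stats::chisq.test(c(males, females), p = c(0.5, 0.5), correct = FALSE)
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = unname(ht$p.value), method = "chi-square goodness-of-fit (1:1)",
             stringsAsFactors = FALSE)
}

#' Reconstruct integer sex counts from a rounded ratio
#'
#' Finds the unique integer pair (m, f) with m + f = `n_sexed` whose ratio
#' m / f rounds (to `decimals` places) to the published `ratio`. Raises a
#' reconstruction error listing candidates if no split or several splits
#' reproduce the ratio.
#'
#' @param ratio published male:female ratio (males per female).
#' @param n_sexed total number of sexed individuals (>= 2).
#' @param decimals decimals the published ratio was rounded to.
#' @return named integer vector `c(males, females)`.
#' @export
reconstruct_counts <- function(ratio, n_sexed, decimals = 2) {
  stopifnot(ratio > 0, n_sexed >= 2)
  m <- seq_len(n_sexed - 1)
  f <- n_sexed - m
  hit <- m[round(m / f, decimals) == round(ratio, decimals)]
  if (length(hit) == 1) {
    return(c(males = hit, females = n_sexed - hit))
  }
  if (length(hit) == 0) {
    stop(sprintf(
      "reconstruction error: no integer split of %d reproduces ratio %.2f",
      n_sexed, ratio))
  }
  stop(sprintf(
    "reconstruction error: ambiguous ratio %.2f of %d (candidates m = %s)",
    ratio, n_sexed, paste(hit, collapse = ", ")))
}

#' Pearson chi-square test for sex-ratio shifts across periods
#'
#' Contingency test of a 2 x k sex-by-period table with expected counts from
#' the margins; df = k - 1.
#'
#' @param counts 2 x k matrix (rows = sexes, columns = periods).
#' @return data.frame with `statistic`, `df`, `p`, `method`.
#' @export
sex_by_period_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2) stop("need a 2 x k table, k >= 2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: zero row or column margin")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = unname(ht$p.value), method = "Pearson chi-square (2 x k)",
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test on total lengths
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return data.frame with `statistic` (t), `df` (Welch), `p` (two-sided),
#'   `method`.
#' @export
length_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) stop("undefined test: zero variance, equal means")
  }
  ht <- stats::t.test(a, b)
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = unname(ht$p.value), method = "Welch two-sample t-test",
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square approximation on k - 1 df.
#' Empty groups are dropped with a warning.
#'
#' @param groups list of numeric vectors.
#' @return data.frame with `statistic` (H), `df`, `p`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty group(s)", sum(empty)))
    groups <- groups[!empty]
  }
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(x) == 0) {
    # all observations identical: H = 0 by convention (full tie correction)
    return(data.frame(statistic = 0, df = length(groups) - 1, p = 1,
                      method = "Kruskal-Wallis rank sum test",
                      stringsAsFactors = FALSE))
  }
  ht <- stats::kruskal.test(x, g)
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = unname(ht$p.value), method = "Kruskal-Wallis rank sum test",
             stringsAsFactors = FALSE)
}

#' Post-hoc multiple comparison of mean ranks after Kruskal-Wallis
#'
#' For every group pair the observed difference in mean ranks is compared
#' with the critical difference
#' \deqn{z_{1 - \alpha / (k(k-1))}\sqrt{\frac{N(N+1)}{12}
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' (two-sided comparisons with a Bonferroni-style k(k-1) divisor shared
#' across pairs).
#'
#' @param groups list of numeric vectors (as [kruskal_wallis()]).
#' @param alpha family significance level.
#' @return data.frame with one row per pair: `group_i`, `group_j`,
#'   `diff_obs`, `diff_crit`, `significant`.
#' @export
kw_posthoc <- function(groups, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty group(s)", sum(empty)))
    groups <- groups[!empty]
  }
  k <- length(groups)
  if (k < 2) stop("need at least 2 non-empty groups")
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x, ties.method = "average")
  g <- rep(seq_len(k), lengths(groups))
  mr <- tapply(rk, g, mean)
  n <- lengths(groups)
  zcrit <- stats::qnorm(1 - alpha / (k * (k - 1)))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      dobs <- abs(mr[i] - mr[j])
      dcrit <- zcrit * sqrt((N * (N + 1) / 12) * (1 / n[i] + 1 / n[j]))
      rows[[length(rows) + 1]] <- data.frame(
        group_i = names(groups)[i], group_j = names(groups)[j],
        diff_obs = unname(dobs), diff_crit = unname(dcrit),
        significant = unname(dobs > dcrit), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length and sex composition summary of a capture table
#'
#' Per-species minimum, maximum, mean and standard deviation of total length
#' plus the male:female ratio among sexed individuals.
#'
#' @param captures data.frame with `species`, `sex` (`"M"`, `"F"`, other =
#'   unsexed), `tl_cm`.
#' @return data.frame with one row per species.
#' @export
summarize_composition <- function(captures) {
  sp <- split(captures, captures$species)
  rows <- lapply(names(sp), function(s) {
    g <- sp[[s]]
    sexed <- g$sex %in% c("M", "F")
    m <- sum(g$sex == "M"); f <- sum(g$sex == "F")
    data.frame(species = s, n_total = nrow(g),
               tl_min = min(g$tl_cm, na.rm = TRUE),
               tl_max = max(g$tl_cm, na.rm = TRUE),
               tl_mean = mean(g$tl_cm, na.rm = TRUE),
               tl_sd = stats::sd(g$tl_cm),
               n_sexed = sum(sexed),
               sex_ratio = if (f > 0) m / f else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
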