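test_that("the 1:1 sex-ratio test matches hand-computed chi-square values", {
  r <- sex_ratio_gof(53, 69)
  expect_equal(round(r$statistic, 3), 2.098)
  expect_equal(r$df, 1)
  expect_equal(round(sex_ratio_gof(51, 65)$statistic, 4), 1.6897)
  expect_equal(sex_ratio_gof(61, 61)$statistic, 0)
  # label-swap invariance and the 2-cell identity (m - f)^2 / n
  expect_equal(sex_ratio_gof(20, 33)$statistic, sex_ratio_gof(33, 20)$statistic)
  expect_equal(sex_ratio_gof(20, 33)$statistic, (20 - 33)^2 / 53)
  expect_error(sex_ratio_gof(0, 0), "undefined")
})

test_that("integer sex counts are reconstructed uniquely from rounded ratios", {
  expect_equal(reconstruct_counts(0.77, 122), c(males = 53, females = 69))
  expect_equal(reconstruct_counts(0.78, 116), c(males = 51, females = 65))
  expect_equal(reconstruct_counts(1.00, 2), c(males = 1, females = 1))
  # the published tiger-shark line is not reproducible by any integer split
  expect_error(reconstruct_counts(0.69, 56), "reconstruction error")
  # ambiguous case: many splits of a large n round to the same ratio
  expect_error(reconstruct_counts(1.00, 1000), "ambiguous")
})

test_that("sex-by-period contingency tests follow the margins", {
  tab <- rbind(c(10, 20), c(20, 10))
  r <- sex_by_period_test(tab)
  expect_equal(round(r$statistic, 3), 6.667)
  expect_equal(r$df, 1)
  same <- rbind(c(12, 12, 12), c(7, 7, 7))
  expect_equal(sex_by_period_test(same)$statistic, 0)
  expect_equal(sex_by_period_test(same)$df, 2)
  expect_error(sex_by_period_test(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(sex_by_period_test(matrix(1:3, 3, 1)), "2 x k")
})

test_that("the contingency test holds its nominal type-I error", {
  set.seed(6)
  rej <- mean(replicate(2000, {
    tab <- rbind(stats::rmultinom(1, 250, rep(0.25, 4))[, 1],
                 stats::rmultinom(1, 250, rep(0.25, 4))[, 1])
    sex_by_period_test(tab)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("the Welch t-test matches the hand formula and its null level", {
  r <- length_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$statistic, 3), -3.674)
  same <- length_ttest(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  set.seed(7)
  rej <- mean(replicate(2000, length_ttest(rnorm(15), rnorm(15))$p < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Kruskal-Wallis reproduces the hand-ranked statistic", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(round(r$statistic, 1), 7.2)
  expect_equal(r$df, 2)
  expect_equal(kruskal_wallis(list(rep(5, 4), rep(5, 3)))$statistic, 0)
  expect_warning(r2 <- kruskal_wallis(list(1:3, numeric(0), 4:6)), "empty")
  expect_equal(r2$df, 1)
  # invariance under strictly monotone transforms of the pooled data
  g <- list(c(0.3, 1.2, 2), c(0.1, 5, 2.2), c(4, 0.5, 3))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(v) exp(v)))$statistic)
})

test_that("the chi-square approximation tracks the exhaustive permutation law", {
  x <- c(3, 5, 9, 1, 2, 4, 8, 7, 6)
  grp <- list(x[1:3], x[4:6], x[7:9])
  r <- kruskal_wallis(grp)
  # brute-force oracle: all 1680 equal-size assignments of the pooled data
  kwH <- function(xx, asg) {
    rk <- rank(xx)
    N <- length(xx)
    12 / (N * (N + 1)) * sum(tapply(rk, asg, sum)^2 / 3) - 3 * (N + 1)
  }
  idx <- utils::combn(9, 3)
  hs <- c()
  for (i in seq_len(ncol(idx))) {
    a <- idx[, i]
    rest <- setdiff(1:9, a)
    jdx <- utils::combn(6, 3)
    for (j in seq_len(ncol(jdx))) {
      asg <- integer(9)
      asg[a] <- 1; asg[rest[jdx[, j]]] <- 2; asg[setdiff(rest, rest[jdx[, j]])] <- 3
      hs <- c(hs, kwH(x, asg))
    }
  }
  p_perm <- mean(hs >= r$statistic - 1e-9)
  expect_lt(abs(p_perm - r$p), 0.02)
})

test_that("the mean-rank post-hoc procedure uses the stated critical difference", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  ph <- kw_posthoc(g, alpha = 0.05)
  expect_equal(nrow(ph), 3)
  # z_{1 - 0.05/6} * sqrt((9 * 10 / 12) * (2/3)) = 5.353
  expect_equal(round(unique(round(ph$diff_crit, 3)), 3), 5.353)
  expect_equal(ph$significant, ph$diff_obs > ph$diff_crit)
  # identical groups: nothing significant
  ph0 <- kw_posthoc(list(a = rep(3, 5), b = rep(3, 5), c = rep(3, 5)))
  expect_false(any(ph0$significant))
  # one clearly shifted group: exactly its two pairs flagged
  g2 <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 100)
  ph2 <- kw_posthoc(g2)
  expect_equal(sum(ph2$significant), 2)
  expect_true(all(grepl("c", paste(ph2$group_i, ph2$group_j)[ph2$significant])))
  # the critical difference grows as alpha shrinks
  expect_true(all(kw_posthoc(g, alpha = 0.01)$diff_crit >
                    kw_posthoc(g, alpha = 0.05)$diff_crit))
})

test_that("capture tables summarize into length/sex composition rows", {
  tr <- default_truths()$blacknose
  caps <- simulate_individuals("blacknose", 300, tr, seed = 8)
  comp <- summarize_composition(caps)
  expect_equal(comp$n_total, 300)
  expect_true(comp$tl_min >= 39 && comp$tl_max <= 180)
  expect_equal(comp$n_sexed, 300)
  expect_gt(comp$sex_ratio, 0.4)
  expect_lt(comp$sex_ratio, 1.2)
})
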