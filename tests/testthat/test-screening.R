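test_that("Fisher-Z intervals reproduce published worked values", {
  # r = 0.342 at n = 464 -> CI [0.259, 0.420]
  z <- atanh(0.342)
  hw <- qnorm(0.975) / sqrt(464 - 3)
  expect_equal(round(tanh(z - hw), 3), 0.259)
  expect_equal(round(tanh(z + hw), 3), 0.420)
  # the same machinery through the user-facing function
  set.seed(1)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  res <- pearson_with_fisher_ci(x, y)
  expect_equal(res$df, 98)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  ct <- stats::cor.test(x, y)           # independent oracle
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$t_stat, unname(ct$statistic))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$ci_low, ct$conf.int[1], tolerance = 1e-10)
  expect_equal(res$ci_high, ct$conf.int[2], tolerance = 1e-10)
})

test_that("perfect and null correlations behave at the boundaries", {
  x <- 1:20
  res <- pearson_with_fisher_ci(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)
  # r = 0: interval symmetric about 0 (oddness of tanh)
  set.seed(2)
  a <- rnorm(50)
  b <- rnorm(50)
  b <- residuals(lm(b ~ a))            # orthogonalize: r exactly 0
  res0 <- pearson_with_fisher_ci(a, b)
  expect_equal(res0$r, 0, tolerance = 1e-12)
  expect_equal(res0$ci_low, -res0$ci_high, tolerance = 1e-12)
})

test_that("degenerate screening inputs raise the stated errors", {
  expect_error(pearson_with_fisher_ci(1:3, 1:3), "at least 4")
  expect_error(pearson_with_fisher_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_rho(rep(2, 8), rnorm(8)), "constant")
})

test_that("t_to_r inverts the correlation t-statistic", {
  expect_equal(round(t_to_r(13.333, 332), 3), 0.591)
  expect_equal(t_to_r(0, 100), 0)
  for (r in seq(-0.9, 0.9, by = 0.2)) {
    df <- 57
    t <- r * sqrt(df / (1 - r^2))
    expect_equal(t_to_r(t, df), r, tolerance = 1e-12)
  }
})

test_that("Spearman uses average ranks and matches the stats oracle", {
  set.seed(3)
  x <- c(1, 2, 2, 3, 4, 4, 4, 7)
  y <- c(5, 3, 4, 4, 1, 2, 2, 0)
  expect_equal(spearman_rho(x, y),
               unname(cor(x, y, method = "spearman")))
  expect_equal(spearman_rho(x, exp(x)), 1)       # monotone transform
  expect_equal(spearman_rho(1:10, 10:1), -1)
})

test_that("the three-criterion rule flags exactly the problematic pairs", {
  # boldfaced row: temp-visib
  expect_true(is_problematic(list(p = 1e-4, ci_low = 0.516, ci_high = 0.656,
                                  s = 0.600)))
  # windspe-winddir: criteria i and ii hold, iii fails
  expect_false(is_problematic(list(p = 1e-4, ci_low = 0.291, ci_high = 0.447,
                                   s = 0.187)))
  expect_false(is_problematic(list(p = 1, ci_low = -0.1, ci_high = 0.1,
                                   s = 0)))
  # sign-agnostic: strong negative correlation flags too
  expect_true(is_problematic(list(p = 1e-4, ci_low = -0.601, ci_high = -0.449,
                                  s = -0.520)))
  # monotone in |s| with all else fixed
  base <- list(p = 0.01, ci_low = 0.25, ci_high = 0.45, s = 0.25)
  stronger <- base; stronger$s <- 0.35
  expect_false(is_problematic(base))
  expect_true(is_problematic(stronger))
})

test_that("screening a covariate table is symmetric, ordered and respects missingness", {
  set.seed(4)
  n <- 200
  d <- data.frame(a = rnorm(n))
  d$b <- 0.8 * d$a + rnorm(n, 0, 0.4)
  d$c <- rnorm(n)
  d$b[1:40] <- NA                       # pairwise-complete handling
  scr <- screen_covariates(d, c("a", "b", "c"))
  expect_equal(scr$cov1, c("a", "a", "b"))
  expect_equal(scr$cov2, c("b", "c", "c"))
  ab <- scr[scr$cov1 == "a" & scr$cov2 == "b", ]
  expect_equal(ab$n, 160)
  expect_equal(ab$df, 158)
  expect_true(ab$problematic)
  expect_false(any(scr$problematic[-1]))
  excl <- attr(scr, "exclusions")
  expect_equal(nrow(excl), 1)
  # symmetry under argument swap
  r1 <- pearson_with_fisher_ci(d$a, d$c)
  r2 <- pearson_with_fisher_ci(d$c, d$a)
  expect_equal(r1$r, r2$r)
  expect_equal(r1$ci_low, r2$ci_low)
  # single covariate: empty result
  expect_equal(nrow(screen_covariates(d, "a")), 0)
})

test_that("the confidence interval tightens with n and always contains r", {
  set.seed(5)
  x <- rnorm(2000); y <- 0.4 * x + rnorm(2000)
  w_small <- with(pearson_with_fisher_ci(x[1:100], y[1:100]),
                  ci_high - ci_low)
  w_big <- with(pearson_with_fisher_ci(x, y), ci_high - ci_low)
  expect_lt(w_big, w_small)
})

test_that("independent covariates are essentially never flagged", {
  flags <- vapply(1:20, function(s) {
    set.seed(100 + s)
    d <- as.data.frame(matrix(rnorm(1000 * 4), ncol = 4))
    any(screen_covariates(d, names(d))$problematic)
  }, TRUE)
  expect_gte(sum(!flags), 18)
})
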