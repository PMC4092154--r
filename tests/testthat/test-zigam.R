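test_that("the penalized IRLS engine reproduces closed-form GLM solutions", {
  # intercept-only Poisson: beta = log(mean) = log(1) = 0
  f <- fit_penalized_glm(c(0, 1, 2), matrix(1, 3, 1), family = "poisson")
  expect_equal(f$beta, 0, tolerance = 1e-8)
  expect_equal(f$edf, 1, tolerance = 1e-8)
  # intercept-only binomial: beta = logit(0.5) = 0
  f2 <- fit_penalized_glm(c(1, 1, 0, 0), matrix(1, 4, 1), family = "binomial")
  expect_equal(f2$beta, 0, tolerance = 1e-8)
  # offset algebra: y = c * hooks exactly -> intercept = log(c)
  hooks <- c(100, 200, 400)
  f3 <- fit_penalized_glm(0.02 * hooks, matrix(1, 3, 1),
                          offset = log(hooks), family = "poisson")
  expect_equal(f3$beta, log(0.02), tolerance = 1e-8)
  expect_error(fit_penalized_glm(1:3, matrix(1, 4, 1)), "rows")
})

test_that("an extreme smoothing parameter collapses the smooth to the linear GLM", {
  set.seed(9)
  n <- 300
  x <- runif(n)
  y <- rpois(n, exp(0.3 + 0.8 * x))
  d <- data.frame(y = y, x = x, effort_hooks = 1)
  f <- fit_gam(model_spec("GAM", "y", list(sm("x", k = 8)),
                          offset = "effort_hooks"), d, lambdas = 1e8)
  g <- stats::glm(y ~ x, poisson)
  expect_lt(max(abs(log(f$fitted_mu) - stats::predict(g))), 1e-4)
  expect_equal(unname(f$edf[["count:s(x)"]]), 1, tolerance = 0.01)
})

test_that("the P-IRLS fit agrees with mgcv at matched smoothing parameters", {
  set.seed(10)
  n <- 400
  x <- runif(n)
  off <- rep(log(50), n)
  y <- rpois(n, exp(off - 4 + sin(2 * pi * x)))
  m <- mgcv::gam(y ~ s(x, k = 8, bs = "tp"), family = poisson,
                 offset = off, method = "REML")
  d <- data.frame(y = y, x = x, effort_hooks = 50)
  f <- fit_gam(model_spec("GAM", "y", list(sm("x", k = 8)),
                          offset = "effort_hooks"), d, lambdas = m$sp)
  # the weak proper prior on the smooth's null-space coefficient shrinks the
  # linear part by O(1e-3) relative to mgcv's fully unpenalized null space
  expect_lt(max(abs(log(f$fitted_mu) - (stats::predict(m) + off))), 5e-3)
})

test_that("a GAM of y = c * hooks recovers log(c) and ignores row order", {
  set.seed(11)
  d <- data.frame(y = as.integer(0.02 * c(100, 200, 400, 100, 300)),
                  effort_hooks = c(100, 200, 400, 100, 300))
  f <- fit_gam(model_spec("GAM", "y", offset = "effort_hooks"), d)
  expect_equal(unname(f$beta[1]), log(0.02), tolerance = 1e-6)
  sv <- make_smooth_survey(300, seed = 12)
  sp <- model_spec("GAM", "y", list(sm("month", k = 6)))
  f1 <- fit_gam(sp, sv$data)
  prm <- sample(nrow(sv$data))
  f2 <- fit_gam(sp, sv$data[prm, ])
  expect_equal(f1$logE, f2$logE, tolerance = 1e-6)
  expect_equal(f1$fitted_mu[prm], f2$fitted_mu, tolerance = 1e-6)
})

test_that("all-zero responses are guarded with a warning", {
  d <- data.frame(y = rep(0L, 20), effort_hooks = 100)
  expect_warning(f <- fit_gam(model_spec("GAM", "y", offset = "effort_hooks"),
                              d), "all-zero")
  expect_true(all(is.finite(f$beta)))
})

test_that("an intercept-only ZIGAM matches the direct two-parameter ZIP MLE", {
  d <- make_zip_data(2000, p = 0.6, mu = 3, seed = 13)
  f <- fit_zigam(model_spec("ZIGAM", "y", offset = "effort_hooks",
                            zero_terms = "intercept"), d)
  nll <- function(th) {
    -sum(ifelse(d$y == 0,
                log((1 - plogis(th[2])) + plogis(th[2]) * exp(-exp(th[1]))),
                log(plogis(th[2])) + dpois(d$y, exp(th[1]), log = TRUE)))
  }
  o <- stats::optim(c(0, 0), nll, method = "BFGS",
                    control = list(reltol = 1e-14))
  expect_lt(abs(f$beta[1] - o$par[1]), 0.01)
  expect_lt(abs(f$gamma[1] - o$par[2]), 0.01)
  expect_lt(abs(f$beta[1] - log(3)), 0.1)
  expect_lt(abs(f$gamma[1] - qlogis(0.6)), 0.1)
  expect_true(all(diff(f$em_trace) > -1e-8))
  expect_true(f$converged)
  expect_lte(f$em_iterations, 250)
})

test_that("ZIGAM degenerates gracefully when the data are plain Poisson", {
  sv <- make_smooth_survey(600, seed = 14)
  sv$truth$zero_baseline <- 40          # regular state with certainty
  sv$data$y <- simulate_catches(sv$data, sv$truth, seed = 15)
  spz <- model_spec("ZIGAM", "y", list(sm("month", k = 6)))
  fz <- suppressWarnings(fit_zigam(spz, sv$data))
  expect_true(all(fz$fitted_p > 0.95))
  spg <- model_spec("GAM", "y", list(sm("month", k = 6)))
  fg <- fit_gam(spg, sv$data)
  expect_lt(max(abs(log(fz$fitted_mu) - log(fg$fitted_mu))), 0.1)
})

test_that("a zero-free response falls back to the GAM with a structural note", {
  set.seed(16)
  d <- data.frame(y = rpois(100, 5) + 1L, effort_hooks = 100)
  f <- fit_zigam(model_spec("ZIGAM", "y", offset = "effort_hooks",
                            zero_terms = "intercept"), d)
  expect_match(f$note, "no zeros")
  expect_true(all(f$fitted_p == 1))
})

test_that("COZIGAM recovers its linkage constants when the constraint is true", {
  set.seed(17)
  n <- 2000
  sc <- scenario(n_nearshore = n, n_cs = 0, seed = 17)
  env <- simulate_environment(sc, seed = 17)
  eta <- log(env$effort_hooks) + log(1.5 / 400) +
    0.8 * sin(2 * pi * (env$month - 3) / 12)
  alpha <- -2; delta <- 1
  p <- plogis(alpha + delta * eta)
  env$y <- rbinom(n, 1, p) * rpois(n, exp(eta))
  f <- fit_cozigam(model_spec("COZIGAM", "y", list(sm("month", k = 6))), env)
  expect_lt(abs(f$alpha - alpha), 0.3)
  expect_lt(abs(f$delta - delta), 0.3)
  expect_true(all(diff(f$em_trace) > -1e-8))
})

test_that("COZIGAM with delta fixed at zero equals the constant-p ZIGAM", {
  sv <- make_smooth_survey(500, seed = 18, p0 = 0.5)
  spc <- model_spec("COZIGAM", "y", list(sm("month", k = 6)))
  spz <- model_spec("ZIGAM", "y", list(sm("month", k = 6)),
                    zero_terms = "intercept")
  fc <- fit_cozigam(spc, sv$data, lambdas = 10, fix_delta = 0)
  fz <- fit_zigam(spz, sv$data, lambdas = 10)
  expect_lt(max(abs(fc$beta - fz$beta)), 1e-2)
  expect_equal(unique(round(fc$fitted_p, 4)),
               unique(round(fz$fitted_p, 4)), tolerance = 1e-3)
})

test_that("the Laplace evidence is deterministic and matches quadrature in 1-D", {
  y2 <- c(0, 1, 2, 1, 0, 3, 1, 0)
  d2 <- data.frame(y = y2, effort_hooks = 1)
  g1 <- fit_gam(model_spec("GAM", "y", offset = "effort_hooks"), d2)
  g2 <- fit_gam(model_spec("GAM", "y", offset = "effort_hooks"), d2)
  expect_identical(log_marginal_likelihood(g1), log_marginal_likelihood(g2))
  ll <- function(b) vapply(b, function(bb)
    exp(sum(dpois(y2, exp(bb), log = TRUE))), 1)
  quad <- log(stats::integrate(ll, -10, 10)$value)
  expect_lt(abs(g1$logE - quad), 0.1)
})

test_that("rescaling effort shifts only the intercept by -log(c)", {
  sv <- make_smooth_survey(400, seed = 19)
  sp <- model_spec("ZIGAM", "y", list(sm("month", k = 6)),
                   zero_terms = "intercept")
  f1 <- fit_zigam(sp, sv$data, lambdas = 10)
  d2 <- sv$data
  d2$effort_hooks <- d2$effort_hooks * 10
  f2 <- fit_zigam(sp, d2, lambdas = 10)
  expect_lt(abs((f1$beta[1] - f2$beta[1]) - log(10)), 1e-3)
  expect_lt(max(abs(f1$beta[-1] - f2$beta[-1])), 1e-3)
})

test_that("fit summaries expose per-term Wald tests and deviance explained", {
  sv <- make_smooth_survey(600, seed = 20, amp = 1.2)
  f <- fit_zigam(model_spec("ZIGAM", "y", list(sm("month", k = 6)),
                            zero_terms = "intercept"), sv$data)
  su <- summarize_fit(f)
  expect_equal(su$term, "count:s(month)")
  expect_lt(su$p, 0.001)
  expect_gt(attr(su, "dev_expl"), 0)
  expect_equal(attr(su, "r2_adj"), f$r2_adj)
  # intercept-only model explains (essentially) no mixture deviance
  f0 <- fit_zigam(model_spec("ZIGAM", "y", zero_terms = "intercept"),
                  sv$data)
  expect_lt(abs(f0$dev_expl), 1e-3)
})

test_that("partial-effect bands cover the truth and contain zero for null terms", {
  grid <- seq(1.5, 11.5, length.out = 25)
  cov_hits <- cov_tot <- zero_hits <- zero_tot <- 0
  for (sd in 1:20) {
    sc <- scenario(n_nearshore = 400, n_cs = 0, seed = 800 + sd)
    env <- simulate_environment(sc)
    tr <- synthetic_truth(
      count_smooths = list(month = function(m) 0.8 * sin(2 * pi * (m - 3) / 12)),
      baseline_log_rate = log(2 / 400), zero_baseline = stats::qlogis(0.55))
    env$y <- simulate_catches(env, tr, seed = 900 + sd)
    # solarrad is absent from the generating truth
    f <- suppressWarnings(fit_zigam(
      model_spec("ZIGAM", "y", list(sm("month", k = 6), sm("solarrad", k = 5)),
                 zero_terms = "intercept"), env))
    pe <- predict_partial(f, "month", grid)
    truthc <- tr$count_smooths$month(grid) -
      mean(tr$count_smooths$month(env$month))
    cov_hits <- cov_hits + sum(pe$lower <= truthc & truthc <= pe$upper)
    cov_tot <- cov_tot + length(grid)
    gs <- seq(min(env$solarrad), max(env$solarrad), length.out = 25)
    pz <- predict_partial(f, "solarrad", gs)
    zero_hits <- zero_hits + sum(pz$lower <= 0 & 0 <= pz$upper)
    zero_tot <- zero_tot + 25
  }
  expect_gte(cov_hits / cov_tot, 0.85)
  expect_gte(zero_hits / zero_tot, 0.90)
})

test_that("partial effects carry positive-width bands and reject unknown terms", {
  sv <- make_smooth_survey(400, seed = 21)
  f <- fit_zigam(model_spec("ZIGAM", "y", list(sm("month", k = 6)),
                            zero_terms = "intercept"), sv$data)
  pe <- predict_partial(f, "month", seq(1, 12, by = 0.5))
  expect_true(all(pe$se > 0))
  expect_true(all(pe$upper > pe$lower))
  expect_false(any(pe$extrapolated))
  expect_error(predict_partial(f, "salinity_of_mars", 1:5), "not found")
})
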