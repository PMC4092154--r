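test_that("basis-dimension optimization follows the curvature of the truth", {
  # strongly sinusoidal truth: a 4-dimensional basis cannot keep up
  sv <- make_smooth_survey(500, seed = 30, amp = 1.5, mean_mu = 3)
  k <- optimize_basis_dim(sv$data, "y", "month", k_grid = c(4, 6, 8),
                          zero_terms = "intercept")
  expect_gte(k, 6)
  expect_equal(names(attr(k, "logE")), c("4", "6", "8"))
  # degenerate grid: the only candidate is returned
  k1 <- optimize_basis_dim(sv$data, "y", "month", k_grid = 6,
                           zero_terms = "intercept")
  expect_equal(as.numeric(k1), 6)
  # all-failure grid raises a selection error (constant covariate)
  sv$data$const <- 1
  expect_error(optimize_basis_dim(sv$data, "y", "const", k_grid = c(4, 6),
                                  zero_terms = "intercept"),
               "selection error")
})

test_that("a linear truth selects the smallest basis dimension", {
  set.seed(31)
  sc <- scenario(n_nearshore = 500, n_cs = 0, seed = 31)
  env <- simulate_environment(sc)
  tr <- synthetic_truth(
    count_smooths = list(temp = function(t) -0.4 * (t - 27.8)),
    baseline_log_rate = log(2 / 400), zero_baseline = stats::qlogis(0.6))
  env$y <- simulate_catches(env, tr, seed = 32)
  k <- optimize_basis_dim(env, "y", "temp", k_grid = c(4, 6, 8),
                          zero_terms = "intercept")
  expect_equal(as.numeric(k), 4)
})

test_that("model-type adjudication records failures as NA and prefers ZIGAM", {
  s <- default_scenario(seed = 33)
  d <- s$cruises
  d$const <- 1                          # unfittable predictor
  adj <- adjudicate_model_type(d, "blacknose", c("temp", "const"), k = 5)
  expect_equal(nrow(adj$table), 2)
  cr <- adj$table[adj$table$predictor == "const", ]
  expect_true(all(is.na(unlist(cr[, c("GAM", "ZIGAM", "COZIGAM")]))))
  tr <- adj$table[adj$table$predictor == "temp", ]
  expect_true(is.finite(tr$ZIGAM) && is.finite(tr$GAM))
  expect_gt(tr$ZIGAM, tr$GAM)
  expect_equal(adj$chosen_type, "ZIGAM")
})

test_that("SPT specifications have the stated structure", {
  specs <- build_spt_specs("nurse", sites = c("BV", "PA", "CS"))
  expect_length(specs$SPT1$smooth_terms, 2)
  expect_equal(sort(unlist(lapply(specs$SPT1$smooth_terms, `[[`, "vars"))),
               c("month", "year"))
  expect_length(specs$SPT2$smooth_terms, 1)
  expect_equal(specs$SPT2$smooth_terms[[1]]$vars, c("year", "month"))
  expect_equal(specs$SPT1$factor_terms, "site")
  expect_error(build_spt_specs("nurse", sites = "BV"), "2 site levels")
})

test_that("evidence distinguishes additive from interacting year-month structure", {
  add_wins <- int_wins <- logical(5)
  for (sd in 1:5) {
    sc <- scenario(n_nearshore = 400, n_cs = 0, seed = 1000 + sd)
    env <- simulate_environment(sc)
    # additive truth: independent year trend and month cycle
    tr_a <- synthetic_truth(count_smooths = list(
      year = function(y) 0.25 * (y - 2008.5),
      month = function(m) 0.7 * sin(2 * pi * (m - 3) / 12)),
      baseline_log_rate = log(2 / 400), zero_baseline = stats::qlogis(0.6))
    env$ya <- simulate_catches(env, tr_a, seed = 1100 + sd)
    # interacting truth: the seasonal cycle reverses across years
    eta <- log(env$effort_hooks) + log(2 / 400) +
      0.9 * sin(2 * pi * (env$month - 3) / 12) *
      cos(pi * (env$year - 2008.5) / 3)
    set.seed(1200 + sd)
    env$yi <- rbinom(nrow(env), 1, 0.6) * rpois(nrow(env), exp(eta))
    fit_both <- function(resp) {
      sp <- build_spt_specs(resp, sites = c("BV", "PA"),
                            model_type = "ZIGAM", k_year = 5, k_month = 6,
                            k_2d = 12)
      list(s1 = suppressWarnings(fit_model(sp$SPT1, env)),
           s2 = suppressWarnings(fit_model(sp$SPT2, env)))
    }
    fa <- fit_both("ya")
    fi <- fit_both("yi")
    add_wins[sd] <- fa$s1$logE > fa$s2$logE
    int_wins[sd] <- fi$s2$logE > fi$s1$logE
  }
  expect_gte(sum(add_wins), 4)
  expect_gte(sum(int_wins), 4)
})

test_that("forward stepwise selection finds the generating covariate and stops", {
  # truth uses temp only; lunday is an independent decoy
  run_one <- function(sd) {
    sc <- scenario(n_nearshore = 500, n_cs = 0, seed = 100 + sd)
    env <- simulate_environment(sc)
    tr <- synthetic_truth(
      count_smooths = list(temp = function(t) -0.5 * (t - 27.8)),
      baseline_log_rate = log(2 / 400), zero_baseline = stats::qlogis(0.5))
    env$y <- simulate_catches(env, tr, seed = 200 + sd)
    forward_stepwise_env(env, "y", candidates = c("temp", "lunday"),
                         site_factor = FALSE, k = 5)
  }
  exact <- vapply(1:10, function(sd) {
    st <- run_one(sd)
    acc <- st$steps[st$steps$accepted, ]
    if (nrow(acc) > 1) expect_true(all(diff(acc$logE) > 0))
    identical(st$included, "temp")
  }, TRUE)
  expect_gte(sum(exact), 8)
  # determinism: identical data and config give an identical trace
  expect_identical(run_one(3)$steps, run_one(3)$steps)
})

test_that("excluded pairs never co-occur, under any candidate order", {
  s <- default_scenario(seed = 35)
  excl <- rbind(c("temp", "visib"))
  for (cand in list(c("temp", "visib"), c("visib", "temp"))) {
    tr <- forward_stepwise_env(s$cruises, "blacknose", candidates = cand,
                               exclusions = excl, k = 5)
    expect_lte(sum(c("temp", "visib") %in% tr$included), 1)
    acc <- tr$steps[tr$steps$accepted, ]
    expect_true(all(diff(c(-Inf, acc$logE)) > 0))
  }
})

test_that("pure-noise candidates leave the environmental model empty", {
  empty <- vapply(1:5, function(sd) {
    sc <- scenario(n_nearshore = 500, n_cs = 0, seed = 300 + sd)
    env <- simulate_environment(sc)
    tr <- synthetic_truth(
      count_smooths = list(temp = function(t) -0.5 * (t - 27.8)),
      baseline_log_rate = log(2 / 400), zero_baseline = stats::qlogis(0.5))
    env$y <- simulate_catches(env, tr, seed = 400 + sd)
    # lunday and tidamp are independent of temp in the generating copula
    st <- forward_stepwise_env(env, "y", candidates = c("lunday", "tidamp"),
                               site_factor = FALSE, k = 5)
    expect_gt(nrow(st$steps), 0)        # evaluations are still recorded
    length(st$included) == 0
  }, TRUE)
  expect_gte(sum(empty), 4)
})

test_that("site-effect Wald tests detect a simulated site contrast", {
  set.seed(37)
  sc <- scenario(n_nearshore = 518, n_cs = 0, seed = 37)
  env <- simulate_environment(sc)
  tr <- synthetic_truth(
    site_effects = c(BV = 0, PA = -1),
    baseline_log_rate = log(2 / 400), zero_baseline = stats::qlogis(0.5))
  env$y <- simulate_catches(env, tr, seed = 38)
  f <- fit_zigam(model_spec("ZIGAM", "y", factor_terms = "site",
                            zero_terms = "intercept"), env)
  st <- site_effect_tests(f)
  expect_equal(st$level, "PA")
  expect_lt(st$Z, -2)
  expect_lt(st$p, 0.05)
  f0 <- fit_zigam(model_spec("ZIGAM", "y", zero_terms = "intercept"), env)
  expect_error(site_effect_tests(f0), "no factor term")
})
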