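# Shared fixtures, built in code at test time.

# Write a small fishing-set CSV and return its path.
write_set_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

example_sets <- function() {
  data.frame(
    cruise_id = c("c1", "c1", "c2", "c3"),
    date = c("2006-03-01", "2006-03-02", "2006-07-10", "2005-06-15"),
    site = c("BV", "BV", "PA", "BV"),
    gear = c("longline", "longline", "longline", "longline"),
    hooks = c(100, 100, 200, 100),
    nurse = c(1, 2, 0, 1),
    blacknose = c(0, 1, 3, 0),
    temp = c(27, 29, NA, 28),
    salin = c(36, 36.4, 35.8, 36.2),
    stringsAsFactors = FALSE
  )
}

# Intercept-only zero-inflated Poisson sample.
make_zip_data <- function(n, p, mu, seed) {
  set.seed(seed)
  y <- stats::rbinom(n, 1, p) * stats::rpois(n, mu)
  data.frame(y = y, effort_hooks = rep(1, n))
}

# Cruise table + counts from a single-smooth truth (month sinusoid) at a
# given survey size; returns data and the generating truth.
make_smooth_survey <- function(n, seed, p0 = 0.5, amp = 0.8,
                               mean_mu = 1.5) {
  sc <- scenario(n_nearshore = n, n_cs = 0, seed = seed)
  env <- simulate_environment(sc, seed = seed)
  tr <- synthetic_truth(
    count_smooths = list(month = function(m) amp * sin(2 * pi * (m - 3) / 12)),
    site_effects = c(BV = 0, PA = 0, CS = 0),
    baseline_log_rate = log(mean_mu / sc$hooks_nearshore),
    zero_baseline = stats::qlogis(p0))
  env$y <- simulate_catches(env, tr, seed = seed + 7)
  list(data = env, truth = tr)
}
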