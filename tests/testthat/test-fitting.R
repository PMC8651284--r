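test_that("log-likelihood matches an independent binomial re-summation", {
  set.seed(21)
  g <- default_levels()
  true <- observer_params(0.1, 0.4)
  probs <- prob_report_noise(c(0, g), true, level_grid(g))
  n <- rep(200L, length(probs))
  N <- rbinom(length(probs), n, probs)
  dat <- psychometric_data(c(0, g), n, N)
  for (par in list(c(0.1, 0.4), c(0, 0.25), c(-0.5, 1))) {
    p_fit <- prob_report_noise(dat$level,
                               observer_params(par[1], par[2]),
                               level_grid(g))
    manual <- sum(lchoose(dat$n_trials, dat$n_noise_reports) +
                    dat$n_noise_reports * log(p_fit) +
                    (dat$n_trials - dat$n_noise_reports) * log(1 - p_fit))
    expect_equal(log_likelihood(dat, par[1], par[2]), manual,
                 tolerance = 1e-10)
  }
  # empty rows contribute nothing; saturated single-row case is ~certain
  d0 <- psychometric_data(c(0, 0.5), c(10L, 0L), c(7L, 0L))
  expect_equal(log_likelihood(d0, 0.1, 0.4),
               dbinom(7, 10, prob_report_noise(0, observer_params(0.1, 0.4),
                                               level_grid(0.5)), log = TRUE))
  expect_gt(log_likelihood(psychometric_data(c(0, 0.5), c(10L, 0L), c(10L, 0L)),
                           20, 0.4), -1e-3)
})

test_that("maximum likelihood recovers the generating parameters", {
  # near-noiseless counts: expected responses at every level
  g <- default_levels()
  true <- observer_params(0.1, 0.4)
  probs <- prob_report_noise(c(0, g), true, level_grid(g))
  big <- psychometric_data(c(0, g), rep(1e5L, length(probs)),
                           as.integer(round(probs * 1e5)))
  fit <- fit_observer(big)
  expect_true(fit$converged)
  expect_lt(abs(fit$prior_logodds_hat - 0.1), 0.05)
  expect_lt(abs(fit$noise_sd_hat - 0.4), 0.02)
  expect_equal(fit$sensitivity, 1 / fit$noise_sd_hat)
  expect_lte(fit$log_likelihood, 0)
  # likelihood dominance: the fit is at least as good as the truth
  expect_gte(fit$log_likelihood + 1e-6, log_likelihood(big, 0.1, 0.4))
})

test_that("the optimum does not depend on the starting point", {
  set.seed(8)
  cfg <- session_config(2000, true_params = observer_params(0.2, 0.5),
                        seed = 77)
  dat <- simulate_session(cfg)$data
  f1 <- fit_observer(dat)
  f2 <- fit_observer(dat, init = c(-1, 1.5))
  expect_equal(f1$prior_logodds_hat, f2$prior_logodds_hat, tolerance = 1e-3)
  expect_equal(f1$noise_sd_hat, f2$noise_sd_hat, tolerance = 1e-3)
})

test_that("degenerate response patterns are boundary-flagged, not errors", {
  all_noise <- psychometric_data(c(0, 0.3, 0.6), c(50L, 50L, 50L),
                                 c(50L, 50L, 50L))
  f <- fit_observer(all_noise)
  expect_true(f$boundary)
  expect_false(f$converged)
  all_struct <- psychometric_data(c(0, 0.3, 0.6), c(50L, 50L, 50L),
                                  c(0L, 0L, 0L))
  expect_true(fit_observer(all_struct)$boundary)
})

test_that("predicted curves are monotone and match the fitted data", {
  set.seed(13)
  cfg <- session_config(4000, true_params = observer_params(0.1, 0.4),
                        seed = 99)
  sess <- simulate_session(cfg)
  fit <- fit_observer(sess$data)
  curve <- predicted_curve(fit)
  expect_equal(curve$level, sess$data$level)
  expect_true(all(diff(curve$p_report_noise) <= 1e-12))
  # fitted curve within 3 binomial SE of the empirical fractions
  emp <- sess$data$n_noise_reports / sess$data$n_trials
  se <- sqrt(curve$p_report_noise * (1 - curve$p_report_noise) /
               sess$data$n_trials)
  expect_true(all(abs(emp - curve$p_report_noise) < 3 * se + 1e-9))
})

test_that("dataset construction and CSV ingestion validate and round-trip", {
  expect_error(psychometric_data(c(0.1, 0.5), c(10, 10), c(5, 5)),
               "level 0")
  expect_error(psychometric_data(c(0, 0.5), c(10, 10), c(11, 5)),
               "n_noise_reports")
  expect_error(psychometric_data(c(0, 0.5, 0.5), c(10, 10, 10), c(5, 5, 5)),
               "distinct")
  tmp <- withr::local_tempfile(fileext = ".csv")
  dat <- psychometric_data(c(0, 0.3, 0.6), c(40L, 30L, 30L), c(30L, 15L, 5L))
  write.csv(dat, tmp, row.names = FALSE)
  expect_equal(read_psychometric_csv(tmp), dat, ignore_attr = TRUE)
  # trial-level CSV is aggregated on load
  trials <- simulate_session(session_config(300, seed = 3))$trials
  write_trials_csv(trials, tmp)
  expect_equal(read_psychometric_csv(tmp), aggregate_trials(trials),
               ignore_attr = TRUE)
})

test_that("fit results serialize to JSON", {
  dat <- psychometric_data(c(0, 0.3, 0.6), c(40L, 30L, 30L), c(30L, 15L, 5L))
  fit <- fit_observer(dat)
  js <- jsonlite::fromJSON(write_fit_json(fit))
  expect_equal(js$noise_sd_hat, fit$noise_sd_hat)
  expect_equal(js$sensitivity, fit$sensitivity)
})
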