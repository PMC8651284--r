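test_that("percept density is a normalized, symmetric truncated Gaussian", {
  for (sd in c(0.1, 0.4, 1.5)) {
    for (s in c(0, 0.5, 0.93)) {
      p <- observer_params(0, sd)
      z <- integrate(function(x) percept_density(x, s, p), -1, 1,
                     rel.tol = 1e-10)$value
      expect_equal(z, 1, tolerance = 1e-8)
    }
  }
  p <- observer_params(0, 0.4)
  xs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(percept_density(xs, 0, p), percept_density(-xs, 0, p))
  expect_equal(percept_density(1.5, 0, p), 0) # outside the domain
  # quadrature-free spot check against the explicit formula
  p2 <- observer_params(0, 0.1)
  manual <- (1 / 0.1) * dnorm(0) /
    (pnorm((1 - 0.5) / 0.1) - pnorm((-1 - 0.5) / 0.1))
  expect_equal(percept_density(0.5, 0.5, p2), manual, tolerance = 1e-12)
  expect_error(observer_params(0, -1), "positive")
})

test_that("percept sampling matches the analytic distribution", {
  p <- observer_params(0, 0.4)
  x <- sample_percept(1e5, 0, p, seed = 4)
  expect_true(all(x >= -1 & x <= 1))
  ks <- suppressWarnings(ks.test(x, function(q) percept_cdf(q, 0, p)))
  expect_lt(unname(ks$statistic), 0.01)
  # degenerate noise collapses onto the true level
  tiny <- sample_percept(100, 0.3, observer_params(0, 1e-9), seed = 1)
  expect_true(all(abs(tiny - 0.3) < 1e-6))
})

test_that("decision variable is strictly decreasing and shifts with the prior", {
  grid <- level_grid()
  xs <- seq(-1, 1, length.out = 1e4)
  set.seed(31)
  for (rep in 1:5) {
    p <- observer_params(runif(1, -2, 2), runif(1, 0.05, 1.5))
    D <- decision_variable(xs, p, grid)
    expect_true(all(diff(D) < 0))
  }
  p0 <- observer_params(0, 0.4)
  p1 <- observer_params(0.7, 0.4)
  expect_equal(decision_variable(xs, p1, grid),
               decision_variable(xs, p0, grid) + 0.7)
  expect_error(decision_variable(0, p0, level_grid(numeric(0))), "at least one")
})

test_that("single-level decision variable reduces to the quadratic form", {
  # with one level and wide bounds, D(x) = alpha - (2 x s1 - s1^2) / (2 sd^2)
  s1 <- 0.5; sd <- 0.25; alpha <- 0.2
  p <- observer_params(alpha, sd, -1e6, 1e6)
  xs <- seq(-0.8, 0.8, length.out = 7)
  expect_equal(decision_variable(xs, p, level_grid(s1)),
               alpha - (2 * xs * s1 - s1^2) / (2 * sd^2), tolerance = 1e-6)
})

test_that("decision boundary matches closed forms and a sign-scan oracle", {
  # wide-bound single level: x* = s1/2 + (sd^2/s1) alpha -> s1/2 at alpha = 0
  p <- observer_params(0, 0.25, -1e6, 1e6)
  expect_equal(decision_boundary(p, level_grid(0.5)), 0.25, tolerance = 1e-6)
  # bounded single level: x* = s1/2 + (sd^2/s1)(alpha + beta)
  s1 <- 0.5; sd <- 0.3; alpha <- 0.2
  pb <- observer_params(alpha, sd)
  beta <- log((pnorm((1 - s1) / sd) - pnorm((-1 - s1) / sd)) /
                (pnorm(1 / sd) - pnorm(-1 / sd)))
  expect_equal(decision_boundary(pb, level_grid(s1)),
               s1 / 2 + sd^2 / s1 * (alpha + beta), tolerance = 1e-8)
  # dense sign-scan oracle on the default grid
  pd <- observer_params(0.1, 0.4)
  g <- level_grid()
  xs <- seq(-1, 1, length.out = 1e6)
  D <- decision_variable(xs, pd, g)
  scan_root <- xs[which(diff(sign(D)) < 0)[1]]
  expect_equal(decision_boundary(pd, g), scan_root, tolerance = 1e-5)
  # clamping in the no-sign-change regimes
  expect_equal(decision_boundary(observer_params(20, 0.4), g), 1)
  expect_equal(decision_boundary(observer_params(-20, 0.4), g), -1)
})

test_that("psychometric probability equals the percept mass on the noise side", {
  g <- level_grid()
  set.seed(5)
  for (rep in 1:4) {
    p <- observer_params(runif(1, -1, 1), runif(1, 0.1, 1))
    xstar <- decision_boundary(p, g)
    for (s in c(0, 0.3, 0.93)) {
      direct <- prob_report_noise(s, p, g)
      quad <- if (xstar > -1) {
        integrate(function(x) percept_density(x, s, p), -1, xstar,
                  rel.tol = 1e-10)$value
      } else 0
      expect_equal(direct, quad, tolerance = 1e-6)
    }
  }
})

test_that("psychometric function is monotone in level and prior", {
  g <- level_grid()
  p <- observer_params(0.1, 0.4)
  s <- c(0, as.numeric(g))
  pr <- prob_report_noise(s, p, g)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr) <= 1e-12))
  for (s0 in c(0, 0.3, 0.93)) {
    pa <- vapply(c(-1, 0, 1, 3), function(a)
      prob_report_noise(s0, observer_params(a, 0.4), g), numeric(1))
    expect_true(all(diff(pa) >= -1e-12))
  }
  # overwhelming noise prior saturates at 1; vanishing noise is a step
  expect_true(all(prob_report_noise(s, observer_params(20, 0.4), g) == 1))
  tiny <- observer_params(0.1, 1e-6)
  expect_equal(prob_report_noise(0, tiny, g), 1)
  expect_equal(prob_report_noise(0.93, tiny, g), 0)
})

test_that("wide-bound single-level model reduces to the cumulative Normal", {
  expect_equal(single_level_closed_form(0.25, 0.5, 0, 0.3), 0.5)
  expect_equal(single_level_closed_form(0.5, 0.5, 0, 0.25), pnorm(-1))
  p <- observer_params(0.3, 0.2, -1e3, 1e3)
  expect_equal(prob_report_noise(0.1, p, level_grid(0.4)),
               single_level_closed_form(0.1, 0.4, 0.3, 0.2),
               tolerance = 1e-6)
  expect_error(single_level_closed_form(0.1, -0.4, 0, 0.2), "positive")
})

test_that("observer params and grid round-trip through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  p <- observer_params(0.17, 0.42)
  g <- level_grid()
  write_observer_json(p, g, tmp)
  back <- read_observer_json(tmp)
  expect_equal(back$params$prior_logodds, 0.17)
  expect_equal(back$params$noise_sd, 0.42)
  expect_equal(as.numeric(back$grid), as.numeric(g))
})
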