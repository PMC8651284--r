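test_that("glider offset tables have the canonical geometry", {
  orders <- c(gamma = 1L, beta_h = 2L, beta_v = 2L, beta_dmain = 2L,
              beta_danti = 2L, theta_tl = 3L, theta_tr = 3L, theta_bl = 3L,
              theta_br = 3L, alpha = 4L)
  for (k in GLIDER_KINDS) {
    off <- glider_offsets(k)
    expect_equal(nrow(off), unname(orders[k]))
    expect_true(all(off %in% 0:1))
    expect_false(anyDuplicated(paste(off[, 1], off[, 2])) > 0)
  }
  expect_equal(glider_offsets("gamma"), cbind(row = 0L, col = 0L))
  expect_equal(glider_offsets("beta_h"), cbind(row = c(0L, 0L), col = c(0L, 1L)))
  expect_equal(glider_offsets("alpha"),
               cbind(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)))
  # theta gliders omit the corner they are named after
  for (k in c("theta_tl", "theta_tr", "theta_bl", "theta_br")) {
    omitted <- switch(k, theta_tl = c(0, 0), theta_tr = c(0, 1),
                      theta_bl = c(1, 0), theta_br = c(1, 1))
    off <- glider_offsets(k)
    expect_false(any(off[, 1] == omitted[1] & off[, 2] == omitted[2]))
  }
  expect_error(glider_offsets("nope"), "unknown glider")
})

test_that("measured statistic agrees with brute-force placement enumeration", {
  set.seed(7)
  for (rep in 1:5) {
    px <- matrix(rbinom(6 * 9, 1, 0.5), 6, 9)
    for (k in GLIDER_KINDS) {
      expect_equal(measure_statistic(as_texture(px), k),
                   brute_statistic(px, k), tolerance = 1e-12)
    }
  }
  # hand-checkable fixed case: six horizontal pairs of a 3x3 image
  px <- rbind(c(1, 0, 1), c(0, 0, 1), c(1, 1, 0))
  expect_equal(measure_statistic(as_texture(px), "beta_h"),
               brute_statistic(px, "beta_h"))
})

test_that("reference textures have the expected statistics", {
  white <- as_texture(matrix(1, 4, 4))
  for (k in GLIDER_KINDS) expect_equal(measure_statistic(white, k), 1)
  checker <- as_texture(outer(1:4, 1:4, function(i, j) (i + j) %% 2))
  expect_equal(measure_statistic(checker, "beta_h"), -1)
  expect_equal(measure_statistic(checker, "alpha"), 1)
  # all-black: spin product is (-1)^order
  black <- statistic_profile(as_texture(matrix(0, 4, 4)))
  expect_equal(unname(black[c("gamma", "theta_tl", "theta_tr", "theta_bl",
                              "theta_br")]), rep(-1, 5))
  expect_equal(unname(black[c("beta_h", "beta_v", "beta_dmain", "beta_danti",
                              "alpha")]), rep(1, 5))
})

test_that("extreme intensities force the parity of every placement", {
  for (k in GLIDER_KINDS) {
    for (g in c(-1, 1)) {
      tex <- generate_texture(texture_spec(k, g, seed = 11))
      expect_equal(measure_statistic(tex, k), g)
    }
  }
})

test_that("generated ensembles calibrate to the requested intensity", {
  for (k in GLIDER_KINDS) {
    expect_within_3se(texture_stat_mean(k, 0.5, 150), 0.5)
  }
  # two-point at the training intensity for one-/two-point statistics
  expect_within_3se(texture_stat_mean("beta_h", 0.85, 200), 0.85)
})

test_that("off-target statistics behave as the ensembles predict", {
  # four-point textures leave lower-order statistics unconstrained
  for (mk in c("gamma", "beta_h", "theta_br")) {
    expect_within_3se(texture_stat_mean("alpha", 0.8, 150, measure_kind = mk), 0)
  }
  # independent rows make the 2x2 parity of a horizontal-pair texture
  # factorize into two row-pair expectations: alpha reading = intensity^2
  expect_within_3se(texture_stat_mean("beta_h", 0.6, 200,
                                      measure_kind = "alpha"), 0.36)
})

test_that("texture generation is seed-deterministic", {
  a <- generate_texture(texture_spec("theta_br", 0.7, seed = 5))
  b <- generate_texture(texture_spec("theta_br", 0.7, seed = 5))
  d <- generate_texture(texture_spec("theta_br", 0.7, seed = 6))
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  expect_false(identical(unclass(a)[, ], unclass(d)[, ]))
  # generation must not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_texture(texture_spec("alpha", 0.5, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("invalid texture specs and measurements are rejected", {
  expect_error(texture_spec("alpha", 1.2), "intensity")
  expect_error(texture_spec("alpha", 0.5, height = 1), "at least")
  expect_error(measure_statistic(as_texture(matrix(1, 1, 4)), "alpha"),
               "smaller than the glider")
  expect_error(as_texture(matrix(c(0, 1, 2, 1), 2, 2)), "exactly 0")
})
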