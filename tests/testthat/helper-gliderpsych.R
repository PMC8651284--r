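# Independent brute-force oracle for the glider statistic: explicit loop
# over every placement, no shared code with measure_statistic().
brute_statistic <- function(pixels, kind) {
  z <- 2 * as.matrix(pixels) - 1
  off <- glider_offsets(kind)
  er <- max(off[, "row"]); ec <- max(off[, "col"])
  vals <- c()
  for (i in seq_len(nrow(z) - er)) {
    for (j in seq_len(ncol(z) - ec)) {
      p <- 1
      for (k in seq_len(nrow(off))) {
        p <- p * z[i + off[k, "row"], j + off[k, "col"]]
      }
      vals <- c(vals, p)
    }
  }
  mean(vals)
}

# mean and 3-standard-error band of a statistic over n generated textures
texture_stat_mean <- function(kind, intensity, n, measure_kind = kind,
                              seed0 = 1000L) {
  vals <- vapply(seq_len(n), function(i) {
    tex <- generate_texture(texture_spec(kind, intensity, seed = seed0 + i))
    measure_statistic(tex, measure_kind)
  }, numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n))
}

expect_within_3se <- function(obj, target) {
  expect_lt(abs(obj$mean - target), 3 * obj$se + 1e-12)
}
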