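#' Ideal-observer parameters
#'
#' The Bayesian ideal observer of the texture-versus-noise task perceives a
#' statistic level `s` as a noisy percept `x`, drawn from a Gaussian of
#' standard deviation `noise_sd` centered on `s` and truncated to the
#' percept domain `[percept_lo, percept_hi]` (statistic values are bounded
#' in `[-1, 1]` by construction, which is the default domain). The observer
#' holds a prior over stimulus category summarized by `prior_logodds`, the
#' log of the prior probability ratio of noise (`s = 0`) to texture
#' (`s > 0`). The inverse noise `1/noise_sd` is the observer's sensitivity.
#'
#' @param prior_logodds Log prior odds of noise vs texture (dimensionless).
#' @param noise_sd Perceptual noise standard deviation, > 0.
#' @param percept_lo,percept_hi Bounds of the percept domain.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(prior_logodds = 0, noise_sd = 0.4,
                            percept_lo = -1, percept_hi = 1) {
  stopifnot(is.numeric(prior_logodds), length(prior_logodds) == 1L,
            is.finite(prior_logodds),
            is.numeric(noise_sd), length(noise_sd) == 1L)
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive", call. = FALSE)
  }
  if (!(percept_lo < percept_hi)) {
    stop("percept_lo must be smaller than percept_hi", call. = FALSE)
  }
  structure(
    list(prior_logodds = prior_logodds, noise_sd = noise_sd,
         percept_lo = percept_lo, percept_hi = percept_hi),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "ideal observer: prior log-odds %.4g, noise sd %.4g (sensitivity %.4g), percept domain [%g, %g]\n",
    x$prior_logodds, x$noise_sd, 1 / x$noise_sd, x$percept_lo, x$percept_hi))
  invisible(x)
}

#' Statistic level grid
#'
#' The discrete set of positive statistic intensities used in the main
#' testing phase. The default grid runs from 0.02 to 0.93 in steps of 0.07
#' plus the maximal level 1.
#'
#' @param levels Strictly increasing positive values in `(0, 1]`.
#' @return Numeric vector of class `level_grid`.
#' @export
level_grid <- function(levels = default_levels()) {
  levels <- as.numeric(levels)
  if (length(levels) < 1L || anyNA(levels)) {
    stop("level grid must contain at least one level", call. = FALSE)
  }
  if (any(levels <= 0) || any(levels > 1)) {
    stop("grid levels must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("grid levels must be strictly increasing", call. = FALSE)
  }
  structure(levels, class = "level_grid")
}

#' @rdname level_grid
#' @export
default_levels <- function() {
  c(seq(0.02, 0.93, by = 0.07), 1)
}

as_grid <- function(grid) {
  if (inherits(grid, "level_grid")) as.numeric(grid) else as.numeric(level_grid(grid))
}

# log(pnorm(hi) - pnorm(lo)) for standard-normal quantiles, computed on
# whichever tail keeps the two probabilities away from 1 so the difference
# survives small sigma.
log_pnorm_diff <- function(lo, hi) {
  flip <- hi < 0
  l <- ifelse(flip, -hi, lo)
  u <- ifelse(flip, -lo, hi)
  lu <- stats::pnorm(u, log.p = TRUE)
  ll <- stats::pnorm(l, log.p = TRUE)
  lu + log1p(-pmin(exp(ll - lu), 1))
}

# log density of the truncated normal percept, vectorized over x and s
log_percept_density <- function(x, s, params) {
  sd <- params$noise_sd
  a <- params$percept_lo; b <- params$percept_hi
  logz <- log_pnorm_diff((a - s) / sd, (b - s) / sd)
  out <- stats::dnorm(x, mean = s, sd = sd, log = TRUE) - logz
  out[x < a | x > b] <- -Inf
  out
}

#' Percept density
#'
#' Density of the truncated-Gaussian percept `x` given the true statistic
#' level `s`: a Normal of mean `s` and sd `noise_sd`, renormalized over the
#' percept domain. Zero outside the domain.
#'
#' @param x Percept value(s).
#' @param s Statistic level.
#' @param params An [observer_params()].
#' @return Density value(s); integrates to 1 over the percept domain.
#' @export
percept_density <- function(x, s, params) {
  exp(log_percept_density(x, s, params))
}

#' Percept cumulative distribution
#'
#' @inheritParams percept_density
#' @return `P(percept <= x | s)`.
#' @export
percept_cdf <- function(x, s, params) {
  sd <- params$noise_sd
  a <- params$percept_lo; b <- params$percept_hi
  x <- pmin(pmax(x, a), b)
  num <- log_pnorm_diff((a - s) / sd, (x - s) / sd)
  den <- log_pnorm_diff((a - s) / sd, (b - s) / sd)
  p <- exp(num - den)
  p[x <= a] <- 0
  pmin(pmax(p, 0), 1)
}

#' Sample percepts
#'
#' Draws from the truncated-Gaussian percept distribution by inverse-CDF
#' sampling, so all draws lie inside the percept domain.
#'
#' @param n Number of draws.
#' @param s Statistic level (scalar, or vector of length `n` for
#'   trial-specific levels).
#' @param params An [observer_params()].
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @return Numeric vector of `n` percepts.
#' @export
sample_percept <- function(n, s, params, seed = NULL) {
  stopifnot(length(s) == 1L || length(s) == n)
  sd <- params$noise_sd
  a <- params$percept_lo; b <- params$percept_hi
  with_seed(seed, {
    plo <- stats::pnorm(a, mean = s, sd = sd)
    phi <- stats::pnorm(b, mean = s, sd = sd)
    u <- stats::runif(n, plo, phi)
    x <- stats::qnorm(u, mean = s, sd = sd)
    pmin(pmax(x, a), b)
  })
}

#' Posterior log-odds decision variable
#'
#' The observer's decision variable for a percept `x` is the posterior
#' log-odds of noise versus texture,
#' `D(x) = prior_logodds + log p(x | s = 0) - log p(x | s > 0)`,
#' where the texture likelihood mixes the truncated-Gaussian percept
#' densities uniformly over the level grid. `D` is strictly decreasing in
#' `x`; the observer reports "noise" exactly when `D(x) > 0`.
#'
#' @param x Percept value(s) within the percept domain.
#' @param params An [observer_params()].
#' @param grid A [level_grid()] of positive statistic levels.
#' @return `D(x)`, vectorized over `x`.
#' @export
decision_variable <- function(x, params, grid) {
  grid <- as_grid(grid)
  K <- length(grid)
  lognum <- log_percept_density(x, 0, params)
  # log of (1/K) sum_k p(x | s_k), via logsumexp over levels
  lp <- vapply(grid, function(sk) log_percept_density(x, sk, params),
               numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1L, max)
  logden <- m + log(rowSums(exp(lp - m))) - log(K)
  params$prior_logodds + lognum - logden
}

#' Decision boundary
#'
#' The percept value `x*` at which the posterior log-odds of noise versus
#' texture crosses zero; percepts below `x*` are reported "noise". `D` is
#' strictly decreasing, so the root is unique when it exists. If `D > 0`
#' over the whole percept domain (e.g. an overwhelming noise prior) the
#' upper bound is returned, and if `D < 0` everywhere the lower bound is
#' returned; these clamps make the psychometric function saturate at 1 and
#' 0 respectively.
#'
#' @inheritParams decision_variable
#' @return The boundary `x*`, a scalar in the percept domain.
#' @export
decision_boundary <- function(params, grid) {
  grid <- as_grid(grid)
  a <- params$percept_lo; b <- params$percept_hi
  Da <- decision_variable(a, params, grid)
  if (Da <= 0) return(a)
  Db <- decision_variable(b, params, grid)
  if (Db >= 0) return(b)
  stats::uniroot(function(x) decision_variable(x, params, grid),
                 interval = c(a, b), f.lower = Da, f.upper = Db,
                 tol = 1e-12)$root
}

#' Psychometric function: probability of reporting "noise"
#'
#' For a true statistic level `s`, the probability that the ideal observer
#' reports "noise" is the truncated-Gaussian percept mass below the
#' decision boundary:
#' `p = [Phi((x* - s)/sd) - Phi((a - s)/sd)] / [Phi((b - s)/sd) - Phi((a - s)/sd)]`
#' with `(a, b)` the percept domain. The function is non-increasing in `s`
#' and non-decreasing in the prior log-odds.
#'
#' @param s Statistic level(s) in `[0, 1]`.
#' @inheritParams decision_variable
#' @return Probability value(s) in `[0, 1]`.
#' @export
prob_report_noise <- function(s, params, grid) {
  xstar <- decision_boundary(params, grid)
  percept_cdf(xstar, s, params)
}

#' Single-level closed-form psychometric function
#'
#' When the observer faces a single texture level `s1` and the percept
#' domain is unbounded, the psychometric function reduces to a cumulative
#' Normal: `p(report noise | s) = Phi(sd/s1 * prior_logodds - (s - s1/2)/sd)`.
#' This equals the bounded model with a one-level grid in the limit of wide
#' percept bounds.
#'
#' @param s Statistic level(s).
#' @param s1 The single positive texture level, > 0.
#' @param prior_logodds Log prior odds of noise vs texture.
#' @param noise_sd Perceptual noise sd, > 0.
#' @return Probability value(s).
#' @export
single_level_closed_form <- function(s, s1, prior_logodds, noise_sd) {
  if (!is.numeric(s1) || s1 <= 0) stop("s1 must be positive", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  stats::pnorm(noise_sd / s1 * prior_logodds - (s - s1 / 2) / noise_sd)
}

#' Serialize observer parameters and grid to JSON
#'
#' @param params An [observer_params()].
#' @param grid A [level_grid()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_observer_json <- function(params, grid, path = NULL) {
  obj <- list(
    prior_logodds = params$prior_logodds,
    noise_sd = params$noise_sd,
    bounds = c(params$percept_lo, params$percept_hi),
    levels = as.numeric(as_grid(grid))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read observer parameters and grid from JSON
#'
#' @param path JSON file produced by [write_observer_json()].
#' @return List with elements `params` ([observer_params()]) and `grid`
#'   ([level_grid()]).
#' @export
read_observer_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  list(
    params = observer_params(obj$prior_logodds, obj$noise_sd,
                             obj$bounds[1], obj$bounds[2]),
    grid = level_grid(obj$levels)
  )
}
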