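#' Per-level psychometric counts
#'
#' Aggregated two-alternative forced-choice data: for each tested statistic
#' level `s` (including the white-noise level `s = 0`), the number of
#' trials and the number of "noise" reports.
#'
#' @param level Statistic levels, distinct, each in `[0, 1]`; must include 0.
#' @param n_trials Trials per level (non-negative integers).
#' @param n_noise_reports "Noise" reports per level, `0 <= N <= T`.
#' @return A data frame of class `psychometric_data`, sorted by level.
#' @seealso [fit_observer()], [aggregate_trials()], [read_psychometric_csv()]
#' @export
psychometric_data <- function(level, n_trials, n_noise_reports) {
  level <- as.numeric(level)
  n_trials <- as.integer(n_trials)
  n_noise_reports <- as.integer(n_noise_reports)
  stopifnot(length(level) == length(n_trials),
            length(level) == length(n_noise_reports))
  if (anyDuplicated(level)) stop("levels must be distinct", call. = FALSE)
  if (any(level < 0) || any(level > 1)) {
    stop("levels must lie in [0, 1]", call. = FALSE)
  }
  if (sum(level == 0) != 1L) {
    stop("data must contain exactly one white-noise (level 0) row",
         call. = FALSE)
  }
  if (any(n_trials < 0L) || any(n_noise_reports < 0L) ||
      any(n_noise_reports > n_trials)) {
    stop("need 0 <= n_noise_reports <= n_trials in every row", call. = FALSE)
  }
  ord <- order(level)
  structure(
    data.frame(level = level[ord], n_trials = n_trials[ord],
               n_noise_reports = n_noise_reports[ord]),
    class = c("psychometric_data", "data.frame")
  )
}

#' Aggregate trial-level records into per-level counts
#'
#' Reduces a trial table (as produced by [simulate_session()] or read from
#' a trial CSV) to the binomial sufficient statistics used for fitting:
#' trials and "noise" reports per level, with noise-category trials pooled
#' at level 0.
#'
#' @param trials Data frame with columns `level` and `response`
#'   (values `"noise"`/`"structured"`).
#' @return A [psychometric_data()] object.
#' @export
aggregate_trials <- function(trials) {
  stopifnot(all(c("level", "response") %in% names(trials)))
  lv <- as.numeric(trials$level)
  noise_rep <- trials$response == "noise"
  agg <- stats::aggregate(cbind(n_trials = rep(1L, length(lv)),
                                n_noise_reports = as.integer(noise_rep)),
                          by = list(level = lv), FUN = sum)
  psychometric_data(agg$level, agg$n_trials, agg$n_noise_reports)
}

#' Read psychometric data from CSV
#'
#' Accepts either aggregated counts (columns
#' `level,n_trials,n_noise_reports`) or trial-level records (columns
#' including `level,response`), which are aggregated on load.
#'
#' @param path CSV file path.
#' @return A [psychometric_data()] object.
#' @export
read_psychometric_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("level", "n_trials", "n_noise_reports") %in% names(df))) {
    return(psychometric_data(df$level, df$n_trials, df$n_noise_reports))
  }
  if (all(c("level", "response") %in% names(df))) {
    return(aggregate_trials(df))
  }
  stop(sprintf(
    "'%s': expected columns level,n_trials,n_noise_reports or level,response",
    path), call. = FALSE)
}

# the grid the observer model uses for a dataset: its positive levels
data_grid <- function(data) {
  level_grid(sort(data$level[data$level > 0]))
}

#' Binomial log-likelihood of psychometric data
#'
#' Sums, over levels, the log binomial probability of the observed "noise"
#' report counts under the ideal-observer psychometric function with the
#' given prior log-odds and noise sd. The observer's level grid is the set
#' of positive levels in the data. Levels with zero trials contribute zero;
#' data that are impossible under the parameters (a report with probability
#' exactly 0) yield `-Inf` rather than an error.
#'
#' @param data A [psychometric_data()] object.
#' @param prior_logodds,noise_sd Observer parameters.
#' @param percept_lo,percept_hi Percept domain bounds.
#' @return Scalar log-likelihood, `<= 0`.
#' @export
log_likelihood <- function(data, prior_logodds, noise_sd,
                           percept_lo = -1, percept_hi = 1) {
  params <- observer_params(prior_logodds, noise_sd, percept_lo, percept_hi)
  grid <- data_grid(data)
  p <- prob_report_noise(data$level, params, grid)
  sum(stats::dbinom(data$n_noise_reports, data$n_trials, p, log = TRUE))
}

#' Fit the ideal-observer model by maximum likelihood
#'
#' Estimates the prior log-odds and perceptual noise sd that maximize the
#' binomial likelihood of per-level "noise" report counts, starting from
#' the initial condition (0.1, 0.4). The search is a derivative-free
#' Nelder--Mead over `(prior_logodds, log noise_sd)` within the box
#' `prior_logodds` in `[-10, 10]`, `noise_sd` in `[1e-3, 10]`, restarted
#' once from its own optimum. The decision boundary is re-solved for every
#' candidate parameter pair.
#'
#' An estimate on the box edge (within 1e-6 of a bound) is flagged
#' `boundary = TRUE` and `converged = FALSE`; this is the expected outcome
#' for degenerate data such as identical responses at every level.
#'
#' @param data A [psychometric_data()] object with at least one positive
#'   level and a level-0 row.
#' @param init Starting values `c(prior_logodds, noise_sd)`.
#' @param lower,upper Box constraints as `c(prior_logodds, noise_sd)`.
#' @param percept_lo,percept_hi Percept domain bounds.
#' @return An object of class `observer_fit`: a list with
#'   `prior_logodds_hat`, `noise_sd_hat`, `sensitivity` (`1/noise_sd_hat`),
#'   `log_likelihood`, `converged`, `boundary`, `n_trials_total`, plus the
#'   fitted `params`, `grid` and the `data`.
#' @export
fit_observer <- function(data, init = c(0.1, 0.4),
                         lower = c(-10, 1e-3), upper = c(10, 10),
                         percept_lo = -1, percept_hi = 1) {
  if (!inherits(data, "psychometric_data")) {
    data <- psychometric_data(data$level, data$n_trials, data$n_noise_reports)
  }
  if (sum(data$level > 0) < 1L) {
    stop("data must contain at least one positive level", call. = FALSE)
  }
  box_lo <- c(lower[1], log(lower[2]))
  box_hi <- c(upper[1], log(upper[2]))
  par0 <- c(init[1], log(init[2]))
  # outside the box, or on the -Inf plateau where the decision boundary is
  # pinned to the domain edge (p identically 0 or 1 with discordant counts),
  # return a large value sloped toward a reference point with an interior
  # boundary so the simplex can escape
  ref <- c(0.1, log(0.4))
  negll <- function(par) {
    if (any(par < box_lo) || any(par > box_hi)) {
      return(1e10 + sum(pmax(par - box_hi, 0)^2) + sum(pmax(box_lo - par, 0)^2))
    }
    ll <- log_likelihood(data, par[1], exp(par[2]), percept_lo, percept_hi)
    if (!is.finite(ll)) return(1e9 + sum((par - ref)^2))
    -ll
  }
  opt <- stats::optim(par0, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  par <- pmin(pmax(opt$par, box_lo), box_hi)
  # complete separation: identical responses at every level leave the
  # likelihood without an interior maximum (a ridge running to the bounds)
  used <- data$n_trials > 0L
  saturated <- all(data$n_noise_reports[used] == data$n_trials[used]) ||
    all(data$n_noise_reports[used] == 0L)
  on_boundary <- saturated ||
    any(abs(par - box_lo) < 1e-6) || any(abs(par - box_hi) < 1e-6)
  alpha_hat <- par[1]
  sigma_hat <- exp(par[2])
  params <- observer_params(alpha_hat, sigma_hat, percept_lo, percept_hi)
  structure(
    list(
      prior_logodds_hat = alpha_hat,
      noise_sd_hat = sigma_hat,
      sensitivity = 1 / sigma_hat,
      log_likelihood = -opt$value,
      converged = opt$convergence == 0L && !on_boundary,
      boundary = on_boundary,
      n_trials_total = sum(data$n_trials),
      params = params,
      grid = data_grid(data),
      data = data
    ),
    class = "observer_fit"
  )
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("ideal-observer fit (maximum likelihood)\n")
  cat(sprintf("  prior log-odds: %8.4f\n", x$prior_logodds_hat))
  cat(sprintf("  noise sd:       %8.4f   (sensitivity 1/sd = %.3f)\n",
              x$noise_sd_hat, x$sensitivity))
  cat(sprintf("  log-likelihood: %8.2f over %d trials\n",
              x$log_likelihood, x$n_trials_total))
  if (!x$converged) {
    cat(sprintf("  NOT converged%s\n",
                if (x$boundary) " (estimate on parameter bound)" else ""))
  }
  invisible(x)
}

#' Predicted psychometric curve from a fit
#'
#' Evaluates the fitted probability of reporting "noise" at the requested
#' statistic levels (use `1 - p` for the fraction classified as
#' structured).
#'
#' @param fit An [fit_observer()] result.
#' @param levels Statistic levels in `[0, 1]`; defaults to the fitted
#'   data's levels.
#' @return Data frame with columns `level` and `p_report_noise`.
#' @export
predicted_curve <- function(fit, levels = fit$data$level) {
  stopifnot(inherits(fit, "observer_fit"))
  data.frame(
    level = levels,
    p_report_noise = prob_report_noise(levels, fit$params, fit$grid)
  )
}

#' Serialize a fit result to JSON
#'
#' @param fit An [fit_observer()] result.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
write_fit_json <- function(fit, path = NULL) {
  obj <- list(
    prior_logodds_hat = fit$prior_logodds_hat,
    noise_sd_hat = fit$noise_sd_hat,
    sensitivity = fit$sensitivity,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    boundary = fit$boundary,
    n_trials_total = fit$n_trials_total
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
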