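#' Configuration of a simulated testing session
#'
#' A session is a sequence of two-alternative forced-choice trials. On each
#' trial the stimulus is white noise or a structured texture with
#' probability `p_structured`, except that at most `max_consecutive` trials
#' of the same category may occur in a row (after a maximal run the other
#' category is forced). Structured trials draw their statistic level
#' uniformly from the level grid; the simulated observer responds by
#' thresholding its noisy percept at the decision boundary.
#'
#' @param n_trials Number of trials.
#' @param grid A [level_grid()] of positive levels.
#' @param true_params The generating [observer_params()].
#' @param p_structured Probability of a structured trial (default 0.5,
#'   the balanced design).
#' @param max_consecutive Cap on same-category run length (2 or 3 in
#'   typical designs).
#' @param seed Optional seed.
#' @return Object of class `session_config`.
#' @export
session_config <- function(n_trials, grid = level_grid(),
                           true_params = observer_params(),
                           p_structured = 0.5, max_consecutive = 3L,
                           seed = NULL) {
  stopifnot(n_trials >= 1, p_structured > 0, p_structured < 1,
            max_consecutive >= 1)
  structure(
    list(n_trials = as.integer(n_trials), grid = level_grid(as.numeric(grid)),
         true_params = true_params, p_structured = p_structured,
         max_consecutive = as.integer(max_consecutive), seed = seed),
    class = "session_config"
  )
}

#' Generate a trial sequence
#'
#' Draws the stimulus category of each trial i.i.d. Bernoulli subject to
#' the run-length cap, and a uniform grid level for each structured trial
#' (level 0 for noise trials).
#'
#' @param config A [session_config()].
#' @return Data frame with columns `trial`, `category`
#'   (`"noise"`/`"structured"`) and `level`.
#' @export
generate_trial_sequence <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials
  with_seed(config$seed, {
    cat_struct <- logical(n)
    run <- 0L
    last <- NA
    for (i in seq_len(n)) {
      if (!is.na(last) && run >= config$max_consecutive) {
        cur <- !last # forced alternation after a maximal run
      } else {
        cur <- stats::runif(1) < config$p_structured
      }
      run <- if (!is.na(last) && cur == last) run + 1L else 1L
      last <- cur
      cat_struct[i] <- cur
    }
    levels <- numeric(n)
    ns <- sum(cat_struct)
    if (ns > 0) {
      levels[cat_struct] <- sample(as.numeric(config$grid), ns, replace = TRUE)
    }
    data.frame(
      trial = seq_len(n),
      category = ifelse(cat_struct, "structured", "noise"),
      level = levels
    )
  })
}

#' Simulate ideal-observer responses
#'
#' For each trial, draws a percept from the truncated Gaussian centered on
#' the trial's level and reports "noise" when the percept falls below the
#' observer's decision boundary (equivalently, when the posterior log-odds
#' of noise is positive). Marginally over percepts this reproduces the
#' analytic psychometric function.
#'
#' @param s Statistic level(s), 0 for noise trials.
#' @param params The generating [observer_params()].
#' @param grid The [level_grid()] the observer assumes.
#' @param seed Optional seed.
#' @return Character vector of responses, `"noise"` or `"structured"`.
#' @export
simulate_response <- function(s, params, grid, seed = NULL) {
  xstar <- decision_boundary(params, grid)
  x <- sample_percept(length(s), s, params, seed = seed)
  ifelse(x < xstar, "noise", "structured")
}

#' Simulate a full testing session
#'
#' Generates a trial sequence, simulates the observer's response on every
#' trial, and aggregates the records into per-level counts ready for
#' [fit_observer()].
#'
#' @param config A [session_config()].
#' @return List with `trials` (data frame: `trial`, `category`, `level`,
#'   `response`, `correct`) and `data` (the aggregated
#'   [psychometric_data()]).
#' @examples
#' cfg <- session_config(500, true_params = observer_params(0.1, 0.4), seed = 1)
#' sess <- simulate_session(cfg)
#' head(sess$trials)
#' @export
simulate_session <- function(config) {
  trials <- generate_trial_sequence(config)
  resp_seed <- derive_seed(config$seed, "responses")
  trials$response <- simulate_response(trials$level, config$true_params,
                                       config$grid, seed = resp_seed)
  trials$correct <- trials$response == trials$category
  data <- aggregate_trials(trials)
  # fitting expects a level-0 row even if no noise trial occurred
  if (!any(data$level == 0)) {
    data <- psychometric_data(c(0, data$level), c(0L, data$n_trials),
                              c(0L, data$n_noise_reports))
  }
  list(trials = trials, data = data)
}

#' Configuration of the adaptive staircase (training phase II)
#'
#' During training the minimum statistic intensity shown to the subject is
#' adapted to performance: structured trials draw a level between the
#' current minimum and `max_level` from a geometric distribution peaked at
#' the minimum; every `window` trials, performance on minimum-level trials
#' is evaluated and the minimum is lowered by `step` when it exceeds
#' `lower_threshold` (0.7) or raised by `step` when it falls below
#' `raise_threshold` (0.5), clipped to `[floor_level, max_level]`.
#'
#' @param max_level Maximum (and initial) intensity: 0.85 for one-/two-point
#'   statistics, 0.95 for three-/four-point.
#' @param start_min_level Initial minimum level (defaults to `max_level`).
#' @param step Staircase step size.
#' @param window Trials between performance evaluations.
#' @param raise_threshold,lower_threshold Performance bounds: below the
#'   first the task is made easier, above the second harder.
#' @param geometric_p Success probability of the (renormalized) geometric
#'   level sampler over level indices ascending from the minimum.
#' @param floor_level Lowest level the staircase may reach.
#' @param n_trials Number of trials to simulate.
#' @param p_structured,max_consecutive As in [session_config()].
#' @param seed Optional seed.
#' @return Object of class `staircase_config`.
#' @export
staircase_config <- function(max_level = 0.95, start_min_level = max_level,
                             step = 0.05, window = 10L,
                             raise_threshold = 0.5, lower_threshold = 0.7,
                             geometric_p = 0.5, floor_level = 0.02,
                             n_trials = 1000L, p_structured = 0.5,
                             max_consecutive = 3L, seed = NULL) {
  stopifnot(raise_threshold > 0, raise_threshold < lower_threshold,
            lower_threshold < 1, step > 0, step < max_level,
            floor_level > 0, floor_level <= start_min_level,
            start_min_level <= max_level, window >= 1, n_trials >= 1,
            geometric_p > 0, geometric_p < 1)
  structure(
    list(max_level = max_level, start_min_level = start_min_level,
         step = step, window = as.integer(window),
         raise_threshold = raise_threshold, lower_threshold = lower_threshold,
         geometric_p = geometric_p, floor_level = floor_level,
         n_trials = as.integer(n_trials), p_structured = p_structured,
         max_consecutive = as.integer(max_consecutive), seed = seed),
    class = "staircase_config"
  )
}

# levels available to the staircase between cur_min and max_level
staircase_levels <- function(cur_min, config) {
  lv <- seq(cur_min, config$max_level + 1e-9, by = config$step)
  pmin(lv, config$max_level)
}

# truncated geometric over level indices, mode at index 1 (the minimum)
sample_staircase_level <- function(levels, p) {
  k <- length(levels)
  w <- p * (1 - p)^(seq_len(k) - 1)
  levels[sample.int(k, 1L, prob = w / sum(w))]
}

#' Simulate the adaptive staircase
#'
#' Runs a simulated subject (an ideal observer with the given parameters)
#' through the phase-II staircase and records the trajectory of the
#' minimum intensity level. The observer's decision boundary is computed
#' on the discretized level range currently in play and updated whenever
#' the range changes. A sensitive observer (small noise sd) drives the
#' minimum down to the floor; a near-chance observer hovers around its
#' starting level.
#'
#' @param config A [staircase_config()].
#' @param true_params The simulated subject's [observer_params()].
#' @return List with `trajectory` (data frame `trial`, `min_level`),
#'   `final_min_level`, and the full `trials` data frame.
#' @export
simulate_staircase <- function(config, true_params) {
  stopifnot(inherits(config, "staircase_config"))
  with_seed(config$seed, {
    cur_min <- config$start_min_level
    levels <- staircase_levels(cur_min, config)
    xstar <- decision_boundary(true_params, level_grid(levels))
    n <- config$n_trials
    min_level <- numeric(n)
    trial_level <- numeric(n)
    category <- character(n)
    response <- character(n)
    run <- 0L; last <- NA
    win_min_n <- 0L; win_min_ok <- 0L; since_update <- 0L
    for (i in seq_len(n)) {
      if (!is.na(last) && run >= config$max_consecutive) {
        struct <- !last
      } else {
        struct <- stats::runif(1) < config$p_structured
      }
      run <- if (!is.na(last) && struct == last) run + 1L else 1L
      last <- struct
      s <- if (struct) sample_staircase_level(levels, config$geometric_p) else 0
      x <- sample_percept(1L, s, true_params)
      resp <- if (x < xstar) "noise" else "structured"
      correct <- (resp == "structured") == struct
      if (struct && abs(s - cur_min) < 1e-9) {
        win_min_n <- win_min_n + 1L
        win_min_ok <- win_min_ok + as.integer(correct)
      }
      trial_level[i] <- s
      category[i] <- if (struct) "structured" else "noise"
      response[i] <- resp
      since_update <- since_update + 1L
      if (since_update >= config$window) {
        if (win_min_n > 0L) {
          perf <- win_min_ok / win_min_n
          new_min <- cur_min
          if (perf > config$lower_threshold) {
            new_min <- max(cur_min - config$step, config$floor_level)
          } else if (perf < config$raise_threshold) {
            new_min <- min(cur_min + config$step, config$max_level)
          }
          if (abs(new_min - cur_min) > 1e-12) {
            cur_min <- new_min
            levels <- staircase_levels(cur_min, config)
            xstar <- decision_boundary(true_params, level_grid(levels))
          }
        }
        win_min_n <- 0L; win_min_ok <- 0L; since_update <- 0L
      }
      min_level[i] <- cur_min
    }
    trials <- data.frame(trial = seq_len(n), category = category,
                         level = trial_level, response = response,
                         correct = (response == "structured") ==
                           (category == "structured"))
    list(
      trajectory = data.frame(trial = seq_len(n), min_level = min_level),
      final_min_level = cur_min,
      trials = trials
    )
  })
}

#' Write trial records to CSV
#'
#' Columns: `trial,category,level,response,correct`.
#'
#' @param trials Trial data frame from [simulate_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(format_csv_num(trials), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# 6 significant digits for CSV artifacts
format_csv_num <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}
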