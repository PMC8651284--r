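# gliderpsych

Visual-psychophysics tools for texture-versus-noise discrimination with
binary textures defined by local multipoint correlations.

Many questions about efficient coding in vision hinge on how sensitive an
observer — human, rodent, or model — is to higher-order spatial
correlations in images. `gliderpsych` covers the full analysis chain for
such experiments:

- **Texture synthesis.** Maximum-entropy binary textures whose multipoint
  statistics are pinned to a chosen intensity. A statistic is defined by a
  *glider*, a template of 1–4 cells inside a 2×2 pixel box (orders denoted
  γ, β, θ, α); its value in a texture is the average over all glider
  placements of the product of spin values (white = +1, black = −1), so
  intensity 0 is white noise and ±1 forces the parity of every placement.
- **Ideal observer.** A Bayesian observer of the two-alternative
  forced-choice task "was this texture structured or white noise?". A true
  level *s* produces a percept *x* from a Gaussian with standard deviation
  σ truncated to [−1, 1]; the observer reports "noise" when the posterior
  log-odds *D(x) = α + ln p(x|s=0) − ln p(x|s>0)* is positive, with α the
  log prior odds of noise. The resulting psychometric function is

  *p(noise | s) = [Φ((x\* − s)/σ) − Φ((−1 − s)/σ)] / [Φ((1 − s)/σ) − Φ((−1 − s)/σ)]*

  where x\* is the unique zero of the (strictly decreasing) decision
  variable. The observer's sensitivity is 1/σ.
- **Model fitting.** Maximum-likelihood estimation of (α, σ) from per-level
  binomial counts of "noise" reports.
- **Behavioral simulation.** Balanced 2AFC sessions with a cap on
  consecutive same-category trials, and the adaptive training staircase
  (geometric level sampling peaked at the current minimum, 10-trial
  performance windows, 70%/50% rules, 0.05 steps).
- **Degree of correspondence.** The cosine similarity between nonnegative
  sensitivity vectors from different observers or data sources, with a
  Monte Carlo p-value under the null of two random directions in the
  positive orthant.

## Worked example

```r
library(gliderpsych)

## a horizontal two-point texture at training intensity 0.85
tex <- generate_texture(texture_spec("beta_h", 0.85, seed = 7))
measure_statistic(tex, "beta_h")
#> [1] 0.8661616    # finite-size sample of the requested 0.85

## simulate a 3000-trial testing session for an observer with
## prior log-odds 0.1 and perceptual noise sd 0.4, then refit it
cfg  <- session_config(3000, true_params = observer_params(0.1, 0.4), seed = 1)
sess <- simulate_session(cfg)
fit  <- fit_observer(sess$data)
fit
#> ideal-observer fit (maximum likelihood)
#>   prior log-odds:   0.1057
#>   noise sd:         0.4042   (sensitivity 1/sd = 2.474)
#>   log-likelihood:   -45.63 over 3000 trials

## compare sensitivity vectors across observers
rat    <- sensitivity_vector(c(beta_h = 4.8, theta = 1.2, alpha = 2.1))
humans <- sensitivity_vector(c(beta_h = 5.2, theta = 1.0, alpha = 2.4))
correspondence_test(rat, humans, n = 1e6, seed = 1)
#> degree of correspondence: c = 0.9984 (p = 0.01016, 1e+06 Monte Carlo null samples)
```

The fit recovers the generating parameters (α = 0.1, σ = 0.4) from the
simulated counts; the correspondence test says the two hypothetical
sensitivity vectors are far more aligned than random positive-orthant
directions.

A thin command-line wrapper with subcommands `textures`, `simulate`,
`staircase`, `fit`, `correspond` and `recover` is installed at
`system.file("cli", "gliderpsych.R", package = "gliderpsych")`; every
subcommand takes `--seed`.

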