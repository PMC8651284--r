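---
title: "Glider textures and the ideal observer: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glider textures and the ideal observer: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliderpsych)
```

This vignette is the package's account of its science: the texture model,
the ideal-observer model and its fitting, the behavioral simulator, and
the correspondence test — together with the numerical and design choices
behind them and what the simulations can and cannot establish.

## Multipoint statistics and maximum-entropy textures

A binary texture is a lattice of black/white pixels, viewed as spins
$z = 2\,\mathrm{pixel} - 1 \in \{-1, +1\}$. A *glider* is a template of
1–4 cells inside a 2×2 box; the texture statistic associated with a
glider is the mean, over all fully-in-bounds placements, of the product of
spins at the glider cells. Ten gliders are supported: the single cell
(`gamma`, order 1), four two-cell pairs (`beta_h`, `beta_v`,
`beta_dmain`, `beta_danti`), four three-cell L shapes (`theta_tl` …
`theta_br`, named after the omitted corner of the box), and the full 2×2
block (`alpha`). A statistic of 0 corresponds to white noise; ±1 forces
the parity of every placement.

**Spin convention.** We fix white = +1 and define intensity as the mean
spin product. For even-order gliders this is exactly the "even number of
white pixels" parity; for odd-order gliders it resolves an ambiguity in
the parity phrasing in favor of the convention under which `gamma = +1`
is an all-white image and positive `theta` intensities produce white L
patterns. The generator accepts signed intensities for every kind; for
three-point statistics, analyses that report only one polarity can take
absolute values at the pipeline level.

**Constructions.** `generate_texture()` samples from the maximum-entropy
ensemble with the requested statistic by local, exactly calibrated
recipes:

- `gamma`: i.i.d. pixels, white with probability $(1+g)/2$;
- `beta_*`: independent Markov chains along the glider axis (rows,
  columns, or diagonals), each seeded with a fair coin, each successive
  spin repeating its predecessor with probability $(1+g)/2$, so adjacent
  spin products have mean $g$. Each diagonal is its own chain, seeded at
  its first in-bounds cell;
- `theta_*`: first row and column fair; remaining cells filled in raster
  order so that each newly completed glider placement has parity $+1$
  with probability $(1+g)/2$. Only the omitted-top-left orientation is
  generated directly; the other three are deterministic horizontal and/or
  vertical flips of that ensemble, which preserve maximum entropy and map
  the glider cells onto the requested orientation;
- `alpha`: first row and column fair;
  $z_{ij} = z_{i-1,j}\, z_{i,j-1}\, z_{i-1,j-1}\, r_{ij}$ with
  $P(r = +1) = (1+g)/2$, so every 2×2 parity has mean $g$.

Each spec carries one integer seed; all draws come from a single seeded
stream in a fixed order, so textures are bit-reproducible, and generation
restores the caller's RNG state. Defaults are 39×22 pixels (the
full-field stimulus format for rodent work, landscape). The test suite
calibrates every kind at intensities 0.2 and 0.5 plus the training
intensities (0.85 for orders 1–2, 0.95 for orders 3–4) over 200 textures,
within three standard errors, and checks the exact-parity limit at
$|g| = 1$.

What the constructions control is the *target* glider's statistic;
off-target statistics follow from the ensemble rather than being forced
to zero. For example, a `beta_h` texture at intensity $g$ has independent
rows, so its `alpha` reading factorizes into two row-pair expectations
and sits at $g^2$ — a property the tests verify by sampling rather than
assume.

## The ideal observer

On each trial the stimulus is white noise ($s = 0$) or a texture with a
level drawn from a grid of $K$ positive values. The observer receives a
percept $x$ from a Gaussian centered on $s$ with standard deviation
$\sigma$, truncated to $[a, b] = [-1, 1]$ — the natural domain, since the
statistic itself is confined there. It holds prior log-odds
$\alpha = \ln p(s{=}0)/p(s{>}0)$ and responds by the sign of the
posterior log-odds

$$D(x) = \alpha + \ln \frac{p(x \mid s = 0)}{\tfrac{1}{K} \sum_k p(x \mid s_k)},$$

which is strictly decreasing in $x$, so the decision rule is a threshold
at the unique root $x^*$ of $D$ and the psychometric function is the
truncated-Gaussian mass below $x^*$:

$$p(\text{noise} \mid s)
  = \frac{\Phi\!\left(\frac{x^* - s}{\sigma}\right) - \Phi\!\left(\frac{-1 - s}{\sigma}\right)}
         {\Phi\!\left(\frac{1 - s}{\sigma}\right) - \Phi\!\left(\frac{-1 - s}{\sigma}\right)}.$$

$1/\sigma$ is the observer's sensitivity — the steepness of this curve.
With a single level and wide bounds the function collapses to a plain
cumulative Normal, $\Phi[\sigma\alpha/s_1 - (s - s_1/2)/\sigma]$, which
the tests use as an independent closed form.

**Level grid.** The default grid is $0.02, 0.09, \dots, 0.93$ (step
0.07) plus 1 — fifteen values. The count is configurable through
`level_grid()`; all computations treat $K$ generically. The observer is
assumed to know the true grid, $\alpha$, $\sigma$ and the bounds — the
standard "ideal" assumption; fitting then inverts the same model.

**Numerical choices.**

- Normalization constants of truncated Gaussians are computed as
  log-differences of `pnorm` values on whichever tail keeps both terms
  away from 1, so densities survive $\sigma$ down to $10^{-6}$ and
  beyond.
- $x^*$ is found by bracketed root-finding (`uniroot`, tolerance
  $10^{-12}$) after a sign check at the domain ends; monotonicity of $D$
  guarantees uniqueness. If $D$ has no sign change — e.g. an overwhelming
  prior — $x^*$ clamps to the corresponding domain end, which makes the
  psychometric function saturate at exactly 0 or 1 instead of failing.
- Percept sampling uses the inverse-CDF construction, so every draw is in
  the domain by construction and the sampler shares no code path with the
  analytic probabilities it is tested against.

## Fitting

Per observer, the likelihood of the per-level counts $(T_s, N_s)$ of
"noise" reports is a product of binomials with success probabilities
given by the psychometric function; `fit_observer()` maximizes the summed
log-likelihood over $(\alpha, \log\sigma)$ by Nelder–Mead from the
starting point $(\alpha, \sigma) = (0.1, 0.4)$, restarted once from its
own optimum, inside the box $\alpha \in [-10, 10]$,
$\sigma \in [10^{-3}, 10]$. Optimizing in $\log\sigma$ keeps the
positivity constraint implicit and roughly symmetrizes the likelihood;
the boundary is re-solved for every candidate parameter pair. Two
non-smooth regimes get explicit handling: outside the box the objective
is a large penalty increasing with the violation, and on the
$-\infty$-likelihood plateau (boundary pinned at a domain end with
discordant counts) it slopes gently back toward a reference point with an
interior boundary so the simplex can escape a poor start. Completely
separated data — identical responses at every level — have no interior
maximum; the fit returns flagged (`boundary = TRUE`, `converged =
FALSE`) rather than erroring. Trial-level records are reduced to
per-level counts before fitting (binomial sufficiency), and arbitrary,
unbalanced per-level trial counts are accepted.

Confidence intervals are deliberately out of scope for the core fit; the
recovery pipeline quantifies estimator spread by replication instead.

## The behavioral simulator

`simulate_session()` emulates the main testing phase: categories i.i.d.
with $P(\text{structured}) = 0.5$ subject to a cap (default 3) on
consecutive same-category trials — after a maximal run the other category
is forced, the simplest scheme honoring the cap, and one that preserves
the 50/50 balance by symmetry; structured levels uniform over the grid;
responses from the percept-threshold rule. The two response routes
(percept threshold vs. Bernoulli at the analytic probability) are
distributionally identical, which the tests check at every grid level.

`simulate_staircase()` emulates the training staircase: structured levels
are drawn between the current minimum and the maximum (0.85 or 0.95, the
training intensity) from a geometric distribution over level indices
ascending from the minimum, renormalized over the finite range. The decay
parameter is not pinned down by the experimental description beyond "peak
at the minimum"; the default success probability of 0.5 concentrates
most trials on the lowest two levels, matching the design's intent of
testing at the edge of ability. Every 10 trials, performance *on
minimum-level trials within the window* is compared to the thresholds:
above 70% correct lowers the minimum by 0.05, below 50% raises it by
0.05, clipped to [0.02, max]. Which trials enter the performance window
is ambiguous in the usual experimental descriptions; restricting to
minimum-level trials (skipping the update when none occurred) is the
reading that makes the 70%/50% thresholds refer to the level actually
under adaptation. The simulated observer's grid is the current staircase
range discretized at the step size, with the decision boundary recomputed
whenever the range changes.

What the simulator does *not* model: learning across sessions, aborted
or ignored trials, reaction times, reward dynamics, texture-pool
bookkeeping, or any stimulus-history effects — percept-level decisions
only. Consequently, passing recovery tests shows the analysis chain is
self-consistent and unbiased *under the model's own assumptions*; it
cannot certify the truncated-Gaussian percept model against real
behavior, where lapses and non-stationarity exist.

## Degree of correspondence

Sensitivity vectors (components $1/\sigma$ per statistic, typically
three shared statistics) are compared by their cosine,
$c(u, v) = u \cdot v / (\|u\| \|v\|)$, confined to $[0, 1]$ for
nonnegative vectors and invariant to overall scaling — appropriate
because sensitivities across observers are expected to match only up to a
gain. Significance comes from a Monte Carlo null: two random directions
in the positive orthant with spherical angles
$\theta_1, \theta_2, \phi_1, \phi_2$ i.i.d. uniform on $[0, \pi/2]$,

$$c_{\text{null}} = \cos\theta_1 \cos\theta_2 +
  \cos(\phi_1 - \phi_2) \sin\theta_1 \sin\theta_2,$$

and the p-value is the fraction of null samples *strictly* greater than
the observed cosine (ties have measure zero). We sample the angles
uniformly — the literal construction above — rather than area-uniformly
on the sphere octant; the two nulls differ, and the angle-uniform one is
the construction whose reported tail probabilities the package
reproduces. The default is $10^7$ samples, drawn in blocks to bound
memory; `scripts/acceptance.R` recomputes the tails at the observed
values 0.986 and 0.990 at that resolution.

```{r null-tails}
monte_carlo_pvalue(0.986, n = 1e6, seed = 1)
monte_carlo_pvalue(0.990, n = 1e6, seed = 1)
```

## Pipeline and reproducibility

`run_recovery_pipeline()` chains simulation and fitting over a table of
synthetic subjects and tabulates true versus estimated parameters; a
failing subject is flagged and skipped, not fatal. `run_correspondence()`
computes all pairwise cosines and p-values among a set of labeled
vectors. Every artifact embeds the full configuration and seed;
per-subject and per-pair seeds are derived deterministically from the
global seed, so any stage can be rerun in isolation and reruns are
byte-identical. Stages communicate only through documented text formats:
PBM/PNG textures, CSV trials and counts, JSON parameters and results.

## Problem sizes in the test suite

The suite exercises the chain at the study's own conditions: 39×22
textures (200 per calibration point), the 15-level grid, $10^5$
simulated responses per level for the analytic-versus-simulation check,
50 replicate 3000-trial sessions per $(\alpha, \sigma)$ cell for
parameter recovery, 20 staircase runs per noise level, 20 replicates of
the four-group ranking pipeline, and $10^6$ null cosines for the tail
probabilities (the acceptance script uses the full $10^7$). These sizes
give Monte Carlo standard errors comfortably below the tolerances they
are tested against.

## Known limitations

- The ideal observer has no lapse or guess rate; real psychometric data
  with asymptotic errors will bias $\sigma$ upward.
- Only one statistic is controlled per texture; joint control of statistic
  pairs is out of scope.
- The correspondence test treats input sensitivity vectors as given
  numbers; uncertainty in those estimates is not propagated into the
  p-value.
- The staircase model reflects one defensible reading of the window
  accounting (minimum-level trials only); alternative readings would
  change trajectories quantitatively but not the monotone dependence of
  the asymptote on sensitivity that the tests check.
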