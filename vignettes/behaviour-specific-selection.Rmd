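---
title: "Behaviour-specific habitat selection: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour-specific habitat selection: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlmove)
```

owlmove analyses high-frequency GPS tracks of central-place foraging
raptors by behavioural mode.  The motivating system is a breeding barn
owl in intensive farmland: 10-s night-only fixes, a nest in a farm
building, and three behavioural modes — perching (stationary), hunting
(slow, tortuous flight) and commuting (fast, straight flight) — each
with its own habitat relationship.  This vignette explains the models
the package implements, the defaults and why they were chosen, what the
synthetic generator does and does not emulate, and the numerical
decisions a user should know about.

## The analysis chain

1. **Filtering and kinematics.** Fixes faster than 15 m/s (well above
   the fastest plausible flight) are removed by deleting the later fix
   of each violating step until no violation remains; a single forward
   pass against the last retained fix reaches that fixpoint, which makes
   the filter idempotent.  Steps are computed within *bursts* (runs of
   fixes with gaps of at most 30 s, i.e. at most two missed fixes):
   step length, speed, absolute heading and signed turning angle.

2. **Behavioural annotation.** Steps are clustered on (speed,
   |turning angle|) with a 4-component bivariate Gaussian mixture fitted
   by expectation-maximization, initialized from the 2×2 partition at
   the per-variable medians.  After convergence the components are
   labelled Low/High on each axis and merged to modes:
   both low-speed regions are perching (a stationary bird moves only
   through GPS error, so its apparent turning angles are arbitrary),
   high-speed/low-turn is commuting, high-speed/high-turn is hunting.
   The 4-to-3 merge rule and the use of |turn| rather than the signed
   angle are design choices: tortuosity is what distinguishes
   behaviour; the sign of a turn is not informative.  The mixture is
   fitted per individual, falling back to a population-pooled fit below
   500 steps, where a per-bird mixture is poorly identified.

3. **Home range.** A bivariate Gaussian kernel density with reference
   bandwidth `sigma * N^(-1/6)`; the 95% isopleth is the smallest-area
   region holding 95% of the mass, extracted on a 25-m grid.  Serial
   autocorrelation is handled by a deliberately simple effective-sample
   correction: the exponential decay time `tau` of the positional
   autocorrelation is fitted from the empirical autocorrelation function
   and `N_eff = N * dt / (dt + 2 tau)` replaces `N` in the bandwidth,
   which can only widen it.  Full autocorrelation-aware machinery
   (movement-model selection, device-error calibration) is intentionally
   out of scope: the home range is consumed downstream only as an
   availability polygon and composition, which are robust to the
   estimator choice.

4. **Third-order selection ratios.** For home-range placement, daylight
   roosting and nocturnal perching, use and availability are compared
   with Manly ratios `w = used/available`, estimated per individual and
   averaged with a normal-approximation 95% CI, with classes excluded
   (and reported) when unavailable or supported by fewer than five use
   events cohort-wide.  Availability is the 1.5-km disc around the nest
   for home-range placement and the home-range composition otherwise.
   Perching events merge runs of consecutive perching steps (at least
   30 s), exclude sites within 50 m of the nest (the nest is not a
   habitat choice) and describe each site by the composition of a 100-m
   disc; events are equally weighted by default, with duration
   weighting available.

5. **Hunting step-selection function.** Hunting runs are thinned to
   30-s steps (weak autocorrelation at that scale), each observed step
   is paired with 100 alternatives (smaller in the fast validation
   runs) built by resampling step lengths and turning angles from the
   pooled observed distribution of the whole cohort, and a conditional
   logistic regression is fitted per bird with eight one-hot habitat
   indicators (cereals as reference — the commonest class, so
   coefficients read as preference relative to ordinary cropland;
   roads and settlements excluded as too rare to estimate) plus step
   length, log step length and cosine of the turning angle.  These
   movement covariates make it an *integrated* SSF: they absorb the
   difference between the resampling pool and the true movement
   kernel.  The Newton solver works on within-stratum-centred
   covariates, reports standard errors from the observed information,
   drops covariates that are constant within every stratum and flags
   monotone-likelihood separation as non-convergence.  A class never
   used by a bird has its likelihood maximized at minus infinity while
   the gradient still vanishes; such poorly estimated classes are
   refitted out of that bird's model and reported missing rather than
   contaminating the population mean.

6. **Commuting path selection.** Commuting runs become paths, typed by
   their endpoints relative to a 50-m nest radius (leave, return,
   within-habitat; out-and-back paths split at their farthest point).
   Only within-habitat paths enter the path-selection function: each is
   compared to 20 rigid copies relocated uniformly within 1.5 km and
   rotated uniformly, with covariates the fractions of the 20-m
   buffered corridor in five grouped classes (intensive open, extensive
   open, forests, forest edges, roads; settlements excluded).
   Fractions rather than absolute areas keep congruent paths
   comparable.  Distance, deviation (path length minus straight-line
   distance) and speed are compared between types with random-intercept
   models (bird as grouping factor) and normal-approximation p-values.

7. **Ordination.** Per-individual hunting coefficients (wildflower
   strips dropped: too few estimable coefficients) are exponentiated to
   relative selection strengths — Bray-Curtis requires non-negative
   data and the exponential is the natural inverse of the log-odds
   scale; a min-shift alternative is provided — and embedded by 3-D
   non-metric multidimensional scaling (monotone regression alternated
   with Guttman-transform updates, best of 20 starts, the first start
   being the metric-scaling solution).  Explanatory variables (date,
   year, sex, age) are tested by permutation against the configuration
   (10,000 permutations), with `r2` from regression on all
   configuration axes for continuous variables and from the
   between-group share of coordinate variance for factors.

## The synthetic generator

`generate_landscape()` tessellates the region into nearest-seed cells of
characteristic size `patch_scale` (default 150 m — arable field scale)
and assigns classes to cells by greedy quota so realized fractions track
the requested composition; classes below 2% are laid down as thin
rectangular strips (10 m wide) instead, emulating sown field-margin AES
strips.  Class queries run against a 5-m lookup raster (also exactly,
from seeds and strips); compositions of discs, isopleths and corridors
are grid-sampled at that resolution, so area fractions carry a ~1%
discretization error — the package's geometric tolerance.  Corridor
*areas* use an exact closed form (the stadium formula with a
`b^2 (tan(tau/2) - tau/2)` correction per joint).

`simulate_tracks()` produces night records from 30 min before dusk to 30
min after dawn at 10-s fixes.  Behaviour follows a 3-state Markov chain
whose self-transitions come from mean dwell times (300/60/45 s) and
whose jump probabilities are solved from flux balance so the stationary
occupancies equal the targets (77.5/12.7/9.8% perching/hunting/
commuting) exactly.  Kinematics: gamma step lengths with mean speeds
4.9 m/s (hunting) and 6.6 m/s (commuting); wrapped-Cauchy turning
angles, wide for hunting (`rho = 0.2`) and concentrated for commuting
(`rho = 0.95`); perching is a fixed point plus GPS noise (3 m), which
makes perching speeds small but nonzero so the clustering problem is
non-trivial.  Hunting endpoints follow the step-selection model's own
generative form — the kinematic proposal tilted by `exp(beta)` of the
endpoint class — realized by rejection sampling.  An earlier
implementation that chose among a fixed candidate set was abandoned:
with finitely many candidates a rare, strongly selected class inflates
its own choice denominator, which suppresses its use by about 0.2
log-odds for a 0.5%-availability class at +1.5 — a subtle but
instructive mismatch with the continuous-availability model the SSF
estimates.  Each night starts and ends at the nest (placed inside a
settlement patch) with a commuting departure and a routed return, so
the three commuting types arise naturally.

What the generator does *not* emulate: terrain, weather and moonlight;
prey distribution within a class; altitude; tag failures and fix
dropouts; inter-individual interaction; habitat change over the season.
Passing the validation experiments therefore demonstrates that the
estimators recover the truth of this generative model at realistic
sizes — not that field data satisfy that model.

## Validation experiments and problem sizes

The `*_experiment()` functions (run by `scripts/acceptance.R` and the
test suite) use sizes chosen to finish in minutes on one core while
keeping the approximations they rely on valid:

- Behaviour recovery: 4 birds × 2 full nights (~45,000 steps), overall
  match against generator truth; the floor is 90%.
- SSF recovery: 30 birds × 800 thinned strata, 20 alternatives.
  Generation is done directly at the 30-s analysis interval with GPS
  noise off, so the generative coefficients are exactly the estimand
  (at 10-s generation plus thinning, or with noise against 10-m-wide
  strips, the estimand would differ from `beta` by construction —
  attenuation effects worth knowing about, but not what this
  experiment measures).
- CI coverage: 50 replicates of 15 birds × 300 strata, 10 alternatives,
  pooled over classes.  Smaller strata counts put so few case events on
  the rarest class that per-bird coefficients are heavy-tailed and the
  normal population interval undercovers; 300 strata is the smallest
  size at which the interval's assumptions hold for all classes.
- PathSF null calibration: 200 replicates of 40 habitat-indifferent
  paths with 20 alternatives each; per-class Wald rejections pooled
  (1000 tests).  Per class separately, 200 binary outcomes are too few
  to resolve a 3-7% band.
- Ordination calibration: 200 simulations, 199 permutations, one
  continuous and one two-level variable (400 tests).
- Home range: 10,000 Gaussian fixes against the closed-form isopleth
  area; Manly neutrality: 10 birds × 10,000 uniform events.

## Numerical choices and degenerate inputs

- EM: covariance ridge `1e-8` times the larger variable variance,
  relative log-likelihood tolerance `1e-6`, 200 iterations; exactly
  degenerate variance in either variable is an error naming the
  variable.  The axis delimiters reported with the labels are
  equal-likelihood boundaries between the Low and High component
  groups, with a midpoint fallback when the densities do not cross.
- Conditional logit: Newton with step halving, gradient tolerance
  `1e-8` (relative), separation flagged at `|beta| > 15`.
- NMDS: stress decrease enforced by step halving toward the previous
  configuration, tolerance `1e-6`; ties in the dissimilarities are
  handled by the stable ordering of the monotone regression.
- Speed filter ties: the *later* fix of a violating step is removed,
  preserving the track origin; chained outliers are caught by the
  fixpoint iteration.
- Off-map handling: alternative step endpoints are redrawn (at most 100
  rounds); null paths are redrawn whole (at most 100 times) and strata
  that still fail are excluded; compositions renormalize over the
  mapped part with a warning.
- All randomness flows through explicit seeds; pipeline stages derive
  sub-seeds from the global seed and the stage name, so toggling stages
  does not shift the randomness of later ones.

## Known limitations

- Compositions are grid-sampled, not polygon-clipped; below ~1% the
  discretization error matters.
- The simplified autocorrelation adjustment can underestimate `N_eff`
  on strongly non-exponential autocorrelation structures; it never
  shrinks the bandwidth below the i.i.d. reference, so home ranges err
  on the smooth side.
- The empirical-pool alternatives inherit the mild selection tilt of
  observed steps; at the default settings this biases strong
  coefficients toward zero by well under 0.1 log-odds, the integrated
  movement covariates absorbing most of the difference.
- Mixed-model p-values use the normal approximation; with few birds
  they are anticonservative.

## A minimal session

```{r example, eval = FALSE}
map <- generate_landscape(seed = 1)
sim <- simulate_tracks(map, truth_config(), n_birds = 4, n_nights = 2,
                       seed = 2)
tracks <- filter_positions(sim$tracks, region = map)$tracks
steps <- derive_kinematics(tracks)
labels <- annotate_behaviour(steps)
validate_against(labels, truth_step_modes(sim, steps))

hr <- estimate_home_range(tracks[tracks$individual_id == "owl001", ])
composition(hr, map)

thinned <- thin_to_interval(steps, 30, labels, "hunting")
cs <- ssf_choice_sets(thinned, map, K = 100, seed = 3)
fit_ssf(cs)$population
```

Or end to end, from a config:

```{r pipeline, eval = FALSE}
run_pipeline(list(seed = 1, out_dir = "owl_run",
                  simulate = list(n_birds = 6, n_nights = 3)))
```
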