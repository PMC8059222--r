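# owlmove

Behaviour-specific habitat selection analysis for GPS-tracked,
central-place foraging raptors — built around the study design used for
breeding barn owls in intensive farmland: high-frequency (10-s),
night-only tracking of birds that roost and breed in farm buildings and
exploit a mosaic of crops, meadows, agri-environment-scheme (AES)
structures, forest and settlement.

The package is aimed at movement ecologists who want the whole analysis
chain in one place, with a synthetic landscape-and-track generator that
provides ground truth for every stage, so each estimator can be
validated before being pointed at field data.

## What it computes

Given timestamped fixes `(id, t, x, y)` in a projected metric frame and
a categorical 10-class habitat map:

- **Position filtering** (speed > 15 m/s, out-of-area) and per-step
  kinematics within bursts: step length, speed, turning angle.
- **Behavioural annotation** by expectation-maximization binary
  clustering on (speed, |turning angle|): a 4-component Gaussian
  mixture whose Low/High × Low/High regions map to perching, hunting
  and commuting.
- **Home ranges**: 95% kernel isopleths with a simplified
  autocorrelation adjustment (`N_eff = N·dt/(dt + 2τ)`), their areas
  and habitat compositions.
- **Manly third-order selection ratios** `w = used/available` for
  home-range placement (availability = 1.5-km disc around the nest),
  daylight roosting and nocturnal perching sites, averaged across
  individuals with 95% CIs.
- **Integrated step-selection function (iSSF)** for hunting: 30-s
  thinning, 100 alternative steps resampled from the population's
  observed step-length/turn distributions, conditional logistic
  regression (Newton-Raphson, authored here) with habitat indicators
  plus step length, log step length and cos(turn); per-bird fits
  averaged to population estimates.
- **Path-selection function (PathSF)** for commuting: flights typed as
  nest-leaving / nest-returning / within-habitat, within-habitat paths
  compared to 20 relocate-and-rotate null paths on the composition of a
  20-m corridor; straightness and speed contrasts between types via
  mixed models.
- **Ordination** of per-individual hunting coefficients: Bray-Curtis
  dissimilarity on exponentiated coefficients, 3-D non-metric MDS
  (Kruskal stress-1), and permutation tests of date, year, sex and age
  against the configuration.

The conditional logit, Bray-Curtis, NMDS and permutation fit are
implemented in the package and cross-checked in the test suite against
independent implementations (`survival`, `vegan`).

## Worked example

```r
library(owlmove)

map <- generate_landscape(seed = 7)          # 4 x 4 km farmland mosaic
cfg <- truth_config()                        # owl-like defaults
sim <- simulate_tracks(map, cfg, n_birds = 3, n_nights = 2, seed = 11)

steps  <- derive_kinematics(sim$tracks)
labels <- embc_cluster(steps)
validate_against(labels, truth_step_modes(sim, steps))
```

```
overall match: 96.2%
 perching   hunting commuting
     99.8      85.2      78.7
```

The clustering recovers 96.2% of the generator's true behavioural modes
overall; perching is nearly perfect, while part of the commuting steps
(fast but briefly tortuous) are labelled hunting — the expected
confusion direction.

```r
tapply(steps$speed, truth_step_modes(sim, steps), mean)
```

```
 perching   hunting commuting
0.5338361 4.8450585 6.5826428
```

Mean speeds by true mode reproduce the configured 4.9 m/s (hunting) and
6.6 m/s (commuting); perching "speed" is pure GPS noise.

```r
hr <- estimate_home_range(sim$tracks[sim$tracks$individual_id == "owl001", ])
hr
round(composition(hr, map), 3)
```

```
<home_range> 95% isopleth: 9.35 km2 (h = 427 m, N_eff = 13 of 6482)
          cereals   root_vegetables          pastures intensive_meadows
            0.273             0.093             0.081             0.102
extensive_meadows wildflower_strips           forests      forest_edges
            0.040             0.005             0.182             0.045
            roads       settlements
            0.088             0.092
```

Two nights of central-place tracking hold only about a dozen
statistically independent locations (`N_eff = 13`), so the
autocorrelation-adjusted bandwidth smooths generously; the composition
is renormalized (with a warning) over the mapped part where the
isopleth spills past the map edge.

An entire run — filtering, annotation, home ranges, the three selection
analyses, SSF, PathSF and ordination, each written as a CSV report with
a provenance header — is one call:

```r
run_pipeline(list(seed = 1, out_dir = "owl_run",
                  simulate = list(n_birds = 6, n_nights = 3)))
```

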