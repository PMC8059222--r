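## Self-validation experiments: each runs the full analysis machinery on
## synthetic data with known truth and returns the quantities a user
## would check before trusting the pipeline on real tracks.  The
## acceptance script and the test suite both run these.

#' Default hunting selection coefficients used by the validation runs
#'
#' Log-odds per modelled class (cereals reference at 0), following the
#' qualitative field pattern: AES structures most preferred, forests
#' avoided, root crops mildly avoided.
#'
#' @return named numeric vector over the eight modelled classes.
#' @export
validation_beta <- function() {
  c(cereals = 0, root_vegetables = -0.4, pastures = 0.3,
    intensive_meadows = 0.8, extensive_meadows = 0.9,
    wildflower_strips = 1.5, forests = -1, forest_edges = 0.4)
}

validation_map <- function(seed) generate_landscape(seed = seed)

## Continuous-hunting configuration at the 30-s analysis scale: the
## generator's per-step choice then coincides with the fitted step scale
## (thinning is the identity) and GPS noise is off so the estimand is
## the generative beta itself.
hunting_cfg <- function(n_steps, beta, interval = 30) {
  truth_config(
    fix_interval = interval, gps_sd = 0, beta = beta,
    night_start_h = 21.5,
    night_end_h = (21.5 + (n_steps + 2) * interval / 3600) %% 24,
    margin = 2 * interval,
    occupancy = c(perching = 0.02, hunting = 0.96, commuting = 0.02),
    dwell = c(perching = 2 * interval, hunting = 1000 * interval,
              commuting = 2 * interval))
}

simulate_hunting_choice_sets <- function(map, beta, n_birds, n_strata, K,
                                         seed, interval = 30) {
  cfg <- hunting_cfg(n_strata + 2, beta, interval)
  sim <- simulate_tracks(map, cfg, n_birds = n_birds, n_nights = 1,
                         seed = seed)
  st <- derive_kinematics(sim$tracks, gap_threshold = interval)
  lab <- data.frame(mode = truth_step_modes(sim, st))
  th <- thin_to_interval(st, interval = interval, labels = lab,
                         mode = "hunting")
  ssf_choice_sets(th, map, K = K, seed = seed + 1)
}

#' Step-selection parameter recovery experiment
#'
#' Simulates a cohort of habitat-biased hunting tracks with known
#' selection coefficients, runs the full integrated step-selection
#' pipeline (thinning, empirical-pool alternatives, per-bird conditional
#' logistic fits, population averaging) and compares the population
#' estimates with the generative truth.
#'
#' @param n_birds,n_strata,K cohort size, observed steps per bird and
#'   alternatives per step.
#' @param beta generative coefficients (default [validation_beta()]).
#' @param seed RNG seed.
#' @return list: `population` estimate table, `errors` (estimate minus
#'   truth per class) and `max_abs_error`.
#' @export
ssf_recovery_experiment <- function(n_birds = 30, n_strata = 800, K = 20,
                                    beta = validation_beta(), seed = 1) {
  map <- validation_map(derive_seed(seed, "recovery-map"))
  cs <- simulate_hunting_choice_sets(map, beta, n_birds, n_strata, K,
                                     derive_seed(seed, "recovery-sim"))
  pop <- fit_ssf(cs)$population
  err <- stats::setNames(pop$mean - beta[pop$class], pop$class)
  list(population = pop, errors = err, max_abs_error = max(abs(err)))
}

#' Step-selection confidence-interval coverage experiment
#'
#' Repeats the recovery experiment at reduced size and measures how
#' often the population-level 95% confidence interval covers the true
#' coefficient, pooled over classes and replicates.
#'
#' @param n_rep replicates.
#' @param n_birds,n_strata,K per-replicate sizes.
#' @param beta generative coefficients.
#' @param seed RNG seed.
#' @return list: `coverage` (pooled), `per_class`, `n_checks`.
#' @export
ssf_coverage_experiment <- function(n_rep = 50, n_birds = 15,
                                    n_strata = 300, K = 10,
                                    beta = validation_beta(), seed = 1) {
  map <- validation_map(derive_seed(seed, "coverage-map"))
  cls <- names(beta)[names(beta) != "cereals"]
  cov <- matrix(NA, n_rep, length(cls), dimnames = list(NULL, cls))
  for (r in seq_len(n_rep)) {
    cs <- simulate_hunting_choice_sets(map, beta, n_birds, n_strata, K,
                                       derive_seed(seed, paste0("cov", r)))
    pop <- fit_ssf(cs)$population
    hit <- (pop$ci_lo <= beta[pop$class]) & (pop$ci_hi >= beta[pop$class])
    cov[r, pop$class[pop$class %in% cls]] <- hit[pop$class %in% cls]
  }
  list(coverage = mean(cov, na.rm = TRUE),
       per_class = colMeans(cov, na.rm = TRUE),
       n_checks = sum(!is.na(cov)))
}

#' Behaviour classification recovery experiment
#'
#' Simulates full nights with the default owl-like kinematics (10-s
#' fixes, 3-m GPS noise, perch/hunt/commute switching), clusters the
#' steps with [embc_cluster()] and scores the labels against the
#' generator truth.
#'
#' @param n_birds,n_nights cohort size.
#' @param seed RNG seed.
#' @return a `validation_report` plus element `overall` in percent.
#' @export
behaviour_recovery_experiment <- function(n_birds = 4, n_nights = 2,
                                          seed = 1) {
  map <- validation_map(derive_seed(seed, "behaviour-map"))
  sim <- simulate_tracks(map, truth_config(), n_birds = n_birds,
                         n_nights = n_nights,
                         seed = derive_seed(seed, "behaviour-sim"))
  st <- derive_kinematics(sim$tracks)
  lab <- embc_cluster(st)
  validate_against(lab, truth_step_modes(sim, st))
}

#' Path-selection null calibration experiment
#'
#' Simulates habitat-indifferent commuting paths (uniform placement,
#' near-straight kinematics), runs the path-selection analysis with 20
#' relocate-and-rotate alternatives per path, and reports the rate at
#' which the per-class Wald tests reject at the 5% level — the type-I
#' error, pooled over classes and replicates.
#'
#' @param n_rep replicates (one bird with `n_paths` paths each).
#' @param n_paths paths per replicate.
#' @param n_alt alternatives per path.
#' @param seed RNG seed.
#' @return list: `type1` (pooled rejection rate), `n_tests`,
#'   `n_failed_fits`.
#' @export
pathsf_null_experiment <- function(n_rep = 200, n_paths = 40, n_alt = 20,
                                   seed = 1) {
  map <- validation_map(derive_seed(seed, "pathsf-map"))
  groups <- names(path_class_groups())
  rej <- integer(0); failed <- 0L
  for (r in seq_len(n_rep)) {
    paths <- with_seed(derive_seed(seed, paste0("paths", r)), {
      lapply(seq_len(n_paths), function(i) {
        x0 <- runif(1, 600, 3400); y0 <- runif(1, 600, 3400)
        hh <- runif(1, 0, 2 * pi) + cumsum(rwrapped_cauchy(7, 0, 0.95))
        len <- stats::rgamma(7, 35, 35 / 66)
        d <- data.frame(t = 10 * (0:7),
                        x = c(x0, x0 + cumsum(len * cos(hh))),
                        y = c(y0, y0 + cumsum(len * sin(hh))))
        attr(d, "individual_id") <- "a"
        attr(d, "path_id") <- paste0("a.p", i)
        attr(d, "type") <- "within_habitat"
        class(d) <- c("commuting_path", "data.frame")
        d
      })
    })
    cs <- path_choice_sets(paths, map, n_alt = n_alt,
                           seed = derive_seed(seed, paste0("alt", r)))
    fit <- fit_clogit(as.matrix(cs[, groups]), cs$is_case, cs$stratum)
    if (!fit$converged || anyNA(fit$se)) { failed <- failed + 1L; next }
    rej <- c(rej, abs(fit$coefficients / fit$se) > 1.96)
  }
  list(type1 = mean(rej), n_tests = length(rej), n_failed_fits = failed)
}

#' Permutation-test calibration experiment for the ordination fit
#'
#' Draws variables independent of a fixed configuration and measures the
#' rejection rate of [envfit_permutation()] at the 5% level, pooled over
#' a continuous and a two-level categorical variable.
#'
#' @param n_sim simulations.
#' @param n individuals in the configuration.
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @return list: `type1`, `n_tests`.
#' @export
envfit_calibration_experiment <- function(n_sim = 200, n = 20,
                                          n_perm = 199, seed = 1) {
  config <- with_seed(derive_seed(seed, "envfit-config"),
                      matrix(stats::rnorm(n * 3), n, 3))
  rej <- logical(0)
  for (s in seq_len(n_sim)) {
    vars <- with_seed(derive_seed(seed, paste0("envfit-var", s)),
                      data.frame(v = stats::rnorm(n),
                                 f = sample(c("u", "w"), n, TRUE)))
    if (length(unique(vars$f)) < 2) vars$f[1:2] <- c("u", "w")
    fit <- envfit_permutation(config, vars, n_perm = n_perm,
                              seed = derive_seed(seed, paste0("envfit-p", s)))
    rej <- c(rej, fit$p <= 0.05)
  }
  list(type1 = mean(rej), n_tests = length(rej))
}

#' Home-range estimator check against the Gaussian closed form
#'
#' The 95% isopleth area of i.i.d. isotropic Gaussian fixes has the
#' closed form `pi * sigma^2 * qchisq(0.95, 2)`.
#'
#' @param n fixes.
#' @param sigma true positional standard deviation (m).
#' @param seed RNG seed.
#' @return list: `area_km2`, `analytic_km2`, `rel_error`.
#' @export
home_range_gaussian_check <- function(n = 10000, sigma = 300, seed = 1) {
  tr <- with_seed(seed, data.frame(
    individual_id = "a",
    t = as.POSIXct("2016-06-01", tz = "UTC") + 10 * seq_len(n),
    x = stats::rnorm(n, 0, sigma), y = stats::rnorm(n, 0, sigma)))
  hr <- estimate_home_range(tr, q = 0.95)
  analytic <- pi * sigma^2 * stats::qchisq(0.95, 2) / 1e6
  list(area_km2 = hr$area_km2, analytic_km2 = analytic,
       rel_error = abs(hr$area_km2 - analytic) / analytic)
}

#' Selection-ratio neutrality experiment
#'
#' Uniform random use on an equal-composition landscape: every
#' population-mean Manly ratio should converge to 1, and the Manly
#' identity `sum(availability * w) = 1` should hold exactly per bird.
#'
#' @param n_birds individuals.
#' @param n_events use events per individual.
#' @param seed RNG seed.
#' @return list: `max_abs_dev` of population means from 1,
#'   `max_identity_dev` of the per-bird Manly identity from 1.
#' @export
manly_uniform_experiment <- function(n_birds = 10, n_events = 10000,
                                     seed = 1) {
  map <- with_seed(derive_seed(seed, "manly-map"), generate_landscape(
    stats::setNames(rep(0.1, 10), habitat_classes()),
    patch_scale = 120, region = c(0, 0, 2000, 2000),
    seed = derive_seed(seed, "manly-map-gen")))
  avail <- class_fractions(map)
  use_list <- with_seed(derive_seed(seed, "manly-use"), {
    lapply(seq_len(n_birds), function(i) {
      px <- runif(n_events, 0, 2000); py <- runif(n_events, 0, 2000)
      tab <- table(habitat_at(map, px, py))
      list(used = stats::setNames(as.numeric(tab) / sum(tab), names(tab)),
           available = avail, n_events = n_events)
    })
  })
  est <- manly_selection(use_list)
  identity_dev <- vapply(use_list, function(u) {
    w <- manly_ratio(u$used, u$available)
    abs(sum(u$available * w, na.rm = TRUE) - 1)
  }, 0)
  list(max_abs_dev = max(abs(est$mean - 1)),
       max_identity_dev = max(identity_dev))
}
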