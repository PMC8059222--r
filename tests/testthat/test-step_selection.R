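# Thinned hunting choice data simulated directly from the discrete-choice
# model on a map: used by the fitting tests.
sim_hunt_steps <- function(map, beta, n_birds, n_steps, seed,
                          interval = 30) {
  cfg <- truth_config(
    fix_interval = interval, gps_sd = 0, beta = beta,
    night_start_h = 21.5,
    night_end_h = (21.5 + (n_steps + 2) * interval / 3600) %% 24,
    margin = 2 * interval,
    occupancy = c(perching = 0.02, hunting = 0.96, commuting = 0.02),
    dwell = c(perching = 2 * interval, hunting = 1000 * interval,
              commuting = 2 * interval))
  sim <- simulate_tracks(map, cfg, n_birds = n_birds, n_nights = 1,
                         seed = seed)
  st <- derive_kinematics(sim$tracks, gap_threshold = interval)
  lab <- data.frame(mode = truth_step_modes(sim, st))
  thin_to_interval(st, interval = interval, labels = lab, mode = "hunting")
}

test_that("thinning keeps every third 10-s fix and is identity at 10 s", {
  tr <- make_track(n = 10, dt = 10, speed = 5)
  st <- derive_kinematics(tr)
  th <- thin_to_interval(st, interval = 30)
  expect_equal(nrow(th), 3)                  # fixes at 0,30,60,90 -> 3 steps
  expect_equal(unique(th$dt), 30)
  expect_equal(unique(th$step_length), 150)
  ident <- thin_to_interval(st, interval = 10)
  expect_equal(nrow(ident), nrow(st))
  expect_equal(ident$step_length, st$step_length)
})

test_that("thinned step lengths equal independent distances", {
  set.seed(1)
  x <- cumsum(rnorm(31, 0, 40)); y <- cumsum(rnorm(31, 0, 40))
  st <- derive_kinematics(track_from_xy(x, y), gap_threshold = Inf)
  th <- thin_to_interval(st, interval = 30)
  keep <- seq(1, 31, by = 3)
  expect_equal(th$step_length,
               sqrt(diff(x[keep])^2 + diff(y[keep])^2))
})

test_that("degenerate pool places all alternatives at the same point", {
  pools <- list(step_length = 100, turn = 0)
  alt <- sample_alternatives(0, 0, prev_heading = 0, pools, K = 10)
  expect_equal(alt$x, rep(100, 10))
  expect_equal(alt$y, rep(0, 10), tolerance = 1e-12)
  expect_error(sample_alternatives(0, 0, 0, list(step_length = numeric(0),
                                                 turn = numeric(0)), 5),
               "empty")
})

test_that("choice sets have K+1 rows per stratum and matched covariates", {
  th <- sim_hunt_steps(fx_map(), c(cereals = 0), 1, 120, seed = 31)
  cs <- ssf_choice_sets(th, fx_map(), K = 100, seed = 1)
  counts <- table(cs$stratum)
  expect_true(all(counts == 101))
  expect_true(all(tapply(cs$is_case, cs$stratum, sum) == 1))
  expect_false(anyNA(cs$habitat[cs$is_case]))
})

test_that("alternative step lengths reproduce the pool distribution", {
  th <- sim_hunt_steps(fx_map(), c(cereals = 0), 2, 120, seed = 32)
  pools <- movement_pools(th)
  cs <- ssf_choice_sets(th, fx_map(), K = 50, seed = 2)
  alt <- cs$step_length[!cs$is_case]
  ks <- suppressWarnings(
    ks.test(sample(alt, min(10000, length(alt))), pools$step_length))
  expect_gt(ks$p.value, 0.01)
})

test_that("null log-likelihood has its closed form", {
  set.seed(3)
  X <- matrix(rnorm(50), 50, 1)
  st <- rep(1:10, each = 5)
  y <- as.logical(ave(seq_len(50), st, FUN = function(i) i == min(i)))
  fit <- fit_clogit(X, y, st, max_iter = 0)
  expect_equal(fit$null_loglik, -10 * log(5), tolerance = 1e-12)
  # beta = 0 evaluation: loglik at start equals the null
  fit2 <- fit_clogit(matrix(0, 50, 1, dimnames = list(NULL, "z")), y, st)
  expect_equal(fit2$loglik, -10 * log(5), tolerance = 1e-12)
})

test_that("two-stratum MLE matches a 1-D grid-search oracle", {
  X <- matrix(c(1, 0, 0, 0, 1, 1), ncol = 1)
  y <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  st <- c(1, 1, 1, 2, 2, 2)
  ll <- function(b) {
    eta <- X[, 1] * b
    sum(tapply(seq_along(eta), st, function(i)
      eta[i][y[i]] - log(sum(exp(eta[i])))))
  }
  grid <- seq(-5, 5, by = 1e-4)
  oracle <- grid[which.max(vapply(grid, ll, 0))]
  fit <- fit_clogit(X, y, st)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), oracle, tolerance = 1e-3)
  expect_equal(ll(fit$coefficients[1]), max(vapply(grid, ll, 0)),
               tolerance = 1e-10)
})

test_that("estimates agree with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(4)
  S <- 80; K <- 5
  st <- rep(1:S, each = K + 1)
  X <- cbind(a = rnorm(S * (K + 1)), b = rbinom(S * (K + 1), 1, 0.4))
  eta <- X %*% c(0.8, -0.5)
  y <- as.logical(unlist(tapply(eta, st, function(e) {
    pick <- sample(length(e), 1, prob = exp(e))
    seq_along(e) == pick
  })))
  fit <- fit_clogit(X, y, st)
  ## one case per stratum: the Breslow partial likelihood equals the
  ## conditional logistic likelihood exactly
  sv <- survival::coxph(
    survival::Surv(rep(1, length(y)), y) ~ a + b + survival::strata(st),
    data = data.frame(X, y = y, st = st), method = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(sv)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sv)))),
               tolerance = 1e-4)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-8)
})

test_that("likelihood is invariant to within-stratum constant shifts", {
  set.seed(5)
  S <- 40; K <- 4
  st <- rep(1:S, each = K + 1)
  X <- cbind(a = rnorm(S * (K + 1)))
  y <- as.logical(ave(seq_along(st), st, FUN = function(i) i == min(i)))
  f1 <- fit_clogit(X, y, st)
  X2 <- X + rep(rnorm(S, 0, 10), each = K + 1)  # per-stratum shift
  f2 <- fit_clogit(X2, y, st)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("constant covariates are dropped and separation flagged", {
  set.seed(6)
  S <- 20; K <- 3
  st <- rep(1:S, each = K + 1)
  y <- as.logical(ave(seq_along(st), st, FUN = function(i) i == min(i)))
  X <- cbind(flat = rep(1, S * (K + 1)), good = rnorm(S * (K + 1)))
  fit <- fit_clogit(X, y, st)
  expect_equal(fit$dropped, "flat")
  # perfectly separating covariate
  Xs <- cbind(sep = as.numeric(y))
  fs <- fit_clogit(Xs, y, st)
  expect_false(fs$converged)
  expect_true(fs$separated)
})

test_that("population averaging recovers generative coefficients", {
  beta <- c(cereals = 0, wildflower_strips = 1.5, extensive_meadows = 0.9,
            forests = -1)
  th <- sim_hunt_steps(fx_map(), beta, n_birds = 10, n_steps = 400,
                       seed = 33)
  cs <- ssf_choice_sets(th, fx_map(), K = 20, seed = 7)
  res <- fit_ssf(cs)
  est <- res$population
  for (cl in c("wildflower_strips", "extensive_meadows", "forests")) {
    row <- est[est$class == cl, ]
    expect_lt(abs(row$mean - beta[[cl]]), 0.35)
  }
  # qualitative ordering: strips and meadows preferred, forests avoided
  expect_gt(est$mean[est$class == "wildflower_strips"],
            est$mean[est$class == "extensive_meadows"])
  expect_gt(est$mean[est$class == "extensive_meadows"],
            est$mean[est$class == "forests"])
})

test_that("larger K reduces the resampling spread of the estimate", {
  beta <- c(cereals = 0, forests = -1)
  th <- sim_hunt_steps(fx_map(), beta, n_birds = 6, n_steps = 200,
                       seed = 34)
  ests <- function(K, seeds) vapply(seeds, function(s) {
    cs <- ssf_choice_sets(th, fx_map(), K = K, seed = s)
    pop <- fit_ssf(cs)$population
    pop$mean[pop$class == "forests"]
  }, 0)
  e_small <- ests(2, 1:10)
  e_large <- ests(25, 1:10)
  expect_gt(sd(e_small, na.rm = TRUE), sd(e_large, na.rm = TRUE))
})
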