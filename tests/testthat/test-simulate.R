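test_that("transition matrix hits the stationary occupancy targets", {
  occ <- c(perching = 0.775, hunting = 0.127, commuting = 0.098)
  P <- owlmove:::solve_transition(occ, c(perching = 300, hunting = 60,
                                         commuting = 45), 10)
  expect_true(all(rowSums(P) - 1 < 1e-12))
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  expect_equal(unname(v / sum(v)), unname(occ), tolerance = 1e-8)
})

test_that("labels align with fixes and timestamps strictly increase", {
  sim <- fx_sim()
  expect_equal(length(sim$true_modes), nrow(sim$tracks))
  for (id in unique(sim$tracks$individual_id)) {
    tt <- sim$tracks$t[sim$tracks$individual_id == id]
    expect_true(all(diff(as.numeric(tt)) > 0))
  }
})

test_that("first and last daily fixes are at the roost in a settlement", {
  sim <- fx_sim()
  meta <- attr(sim$tracks, "meta")
  for (id in unique(sim$tracks$individual_id)) {
    tr <- sim$tracks[sim$tracks$individual_id == id, ]
    nest <- unlist(meta[meta$individual_id == id, c("nest_x", "nest_y")])
    expect_equal(unname(habitat_at(sim$map, nest[1], nest[2])),
                 factor("settlements", habitat_classes()),
                 ignore_attr = TRUE)
    tt <- as.numeric(tr$t)
    night <- cumsum(c(1, as.integer(diff(tt) > 3600)))
    for (ng in unique(night)) {
      ni <- which(night == ng)
      ends <- c(ni[1], ni[length(ni)])
      d <- sqrt((tr$x[ends] - nest[1])^2 + (tr$y[ends] - nest[2])^2)
      expect_true(all(d < 20))  # roost position up to GPS noise
    }
  }
})

test_that("per-mode empirical speeds reproduce the configuration", {
  cfg <- truth_config(night_start_h = 22, night_end_h = 2)
  sim <- simulate_tracks(fx_map(), cfg, n_birds = 6, n_nights = 3,
                         seed = 515)
  st <- derive_kinematics(sim$tracks)
  tm <- truth_step_modes(sim, st)
  sp <- tapply(st$speed, tm, mean)
  expect_equal(unname(sp[["hunting"]]), 4.9, tolerance = 0.3 / 4.9)
  expect_equal(unname(sp[["commuting"]]), 6.6, tolerance = 0.3 / 6.6)
  expect_lt(sp[["perching"]], 1)          # GPS-noise speeds
  expect_lt(sp[["hunting"]], sp[["commuting"]])
  occ <- prop.table(table(tm))
  expect_gt(occ[["perching"]], 0.70)      # roost margins add perching
  expect_equal(unname(occ[["hunting"]] / occ[["commuting"]]),
               0.127 / 0.098, tolerance = 0.25)
})

test_that("commuting segments are near-straight", {
  sim <- fx_sim(); st <- fx_steps(); tm <- fx_truth()
  comm <- which(tm == "commuting" & is.finite(st$turning_angle))
  expect_lt(median(abs(st$turning_angle[comm])), 0.3)
  hunt <- which(tm == "hunting" & is.finite(st$turning_angle))
  expect_gt(median(abs(st$turning_angle[hunt])), 0.5)
})

test_that("a fixed seed regenerates identical data", {
  cfg <- truth_config(night_start_h = 23, night_end_h = 0.5)
  a <- simulate_tracks(fx_map(), cfg, n_birds = 2, n_nights = 1, seed = 99)
  b <- simulate_tracks(fx_map(), cfg, n_birds = 2, n_nights = 1, seed = 99)
  expect_identical(a$tracks$x, b$tracks$x)
  expect_identical(a$true_modes, b$true_modes)
  c <- simulate_tracks(fx_map(), cfg, n_birds = 2, n_nights = 1, seed = 100)
  expect_false(identical(a$tracks$x, c$tracks$x))
})

test_that("a map without settlements cannot host a roost", {
  m <- generate_landscape(c(cereals = 1), region = c(0, 0, 1000, 1000),
                          patch_scale = 200, seed = 1)
  expect_error(simulate_tracks(m, truth_config(), 1, 1, seed = 1),
               "no settlements patch")
})

test_that("unbiased hunting endpoints match availability", {
  cfg <- truth_config(night_start_h = 22, night_end_h = 2,
                      beta = c(cereals = 0))
  sim <- simulate_tracks(fx_map(), cfg, n_birds = 5, n_nights = 2,
                         seed = 606)
  hunt <- sim$true_modes == "hunting"
  cl <- habitat_at(sim$map, sim$tracks$x[hunt], sim$tracks$y[hunt])
  n <- sum(!is.na(cl))
  use <- table(cl) / n
  avail <- class_fractions(sim$map)
  # trajectory autocorrelation makes the effective sample much smaller
  # than the fix count, so allow a margin beyond the binomial error
  for (cn in c("cereals", "forests", "intensive_meadows")) {
    se <- sqrt(avail[[cn]] * (1 - avail[[cn]]) / n)
    expect_lt(abs(use[[cn]] - avail[[cn]]), 4 * se + 0.02)
  }
})

test_that("hunting endpoint odds reproduce the selection coefficient", {
  # direct counting oracle on the generator's own output: strips at
  # +1.5 log-odds versus cereals at 0
  # gps_sd = 0: observation noise throws endpoints off the 10-m strips
  # and would attenuate the measured odds, which is not what this
  # counting oracle checks
  cfg <- truth_config(
    night_start_h = 21.5, night_end_h = 5.5, fix_interval = 10, gps_sd = 0,
    beta = c(wildflower_strips = 1.5, cereals = 0),
    occupancy = c(perching = 0.05, hunting = 0.9, commuting = 0.05),
    dwell = c(perching = 30, hunting = 600, commuting = 30))
  sim <- simulate_tracks(fx_map(), cfg, n_birds = 6, n_nights = 3,
                         seed = 707)
  hunt <- sim$true_modes == "hunting"
  expect_gt(sum(hunt), 45000)
  cl <- habitat_at(sim$map, sim$tracks$x[hunt], sim$tracks$y[hunt])
  avail <- class_fractions(sim$map)
  n_str <- sum(cl == "wildflower_strips", na.rm = TRUE)
  n_cer <- sum(cl == "cereals", na.rm = TRUE)
  log_or <- log((n_str / n_cer) /
                  (avail[["wildflower_strips"]] / avail[["cereals"]]))
  se <- sqrt(1 / n_str + 1 / n_cer)
  expect_equal(log_or, 1.5, tolerance = (3 * se + 0.1) / 1.5)
})
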