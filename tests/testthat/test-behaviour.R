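# Synthetic step series with the three kinematic signatures: stationary
# GPS noise, slow tortuous flight, fast straight flight.
make_mode_steps <- function(n_perch = 1500, n_hunt = 400, n_comm = 300,
                            seed = 1) {
  set.seed(seed)
  speed <- c(abs(rnorm(n_perch, 0.2, 0.1)),
             pmax(rnorm(n_hunt, 4.9, 1.0), 0.3),
             pmax(rnorm(n_comm, 6.6, 1.1), 0.3))
  turn <- c(runif(n_perch, -pi, pi),
            owlmove:::rwrapped_cauchy(n_hunt, 0, 0.2),
            owlmove:::rwrapped_cauchy(n_comm, 0, 0.95))
  truth <- factor(rep(c("perching", "hunting", "commuting"),
                      c(n_perch, n_hunt, n_comm)),
                  levels = c("perching", "hunting", "commuting"))
  steps <- data.frame(individual_id = "a", burst_id = "a.b1",
                      speed = speed, turning_angle = turn,
                      dt = 10, step_length = speed * 10)
  list(steps = steps, truth = truth)
}

test_that("well-separated modes are recovered at 90%+", {
  d <- make_mode_steps()
  lab <- embc_cluster(d$steps)
  rep <- validate_against(lab, d$truth)
  expect_gt(rep$overall, 90)
  p <- attr(lab, "params")
  expect_equal(sum(p$weights), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  d <- make_mode_steps(seed = 2)
  p <- attr(embc_cluster(d$steps), "params")
  expect_true(all(diff(p$loglik) > -1e-6))
  expect_true(p$converged)
})

test_that("near-degenerate one-mode input still yields a total mapping", {
  set.seed(3)
  steps <- data.frame(individual_id = "a", burst_id = "a.b1",
                      speed = 1 + rnorm(400, 0, 1e-3),
                      turning_angle = 0.5 + rnorm(400, 0, 1e-3),
                      dt = 10, step_length = 10)
  lab <- embc_cluster(steps)
  expect_false(anyNA(lab$mode))
  # all four components collapse onto the single blob
  p <- attr(lab, "params")
  mus <- do.call(rbind, p$means)
  expect_true(all(abs(mus[, 1] - 1) < 0.05))
  expect_true(all(abs(mus[, 2] - 0.5) < 0.05))
})

test_that("exactly degenerate variance errors name the variable", {
  steps <- data.frame(individual_id = "a", burst_id = "b",
                      speed = rep(1, 50), turning_angle = runif(50, -3, 3),
                      dt = 10, step_length = 10)
  expect_error(embc_cluster(steps), "speed")
  steps2 <- data.frame(individual_id = "a", burst_id = "b",
                       speed = runif(50, 0, 5), turning_angle = 0.3,
                       dt = 10, step_length = 10)
  expect_error(embc_cluster(steps2), "turning")
})

test_that("speed delimiter approximates the analytic two-Gaussian boundary", {
  set.seed(11)
  n <- 3000
  comp <- rbinom(n, 1, 0.5)
  speed <- ifelse(comp == 1, rnorm(n, 5, 0.8), abs(rnorm(n, 1, 0.3)))
  steps <- data.frame(individual_id = "a", burst_id = "b", speed = speed,
                      turning_angle = 0.5 + rnorm(n, 0, 0.02),
                      dt = 10, step_length = speed * 10)
  lab <- embc_cluster(steps)
  split <- attr(lab, "params")$delimiters[["speed"]]
  boundary <- uniroot(function(x)
    dnorm(x, 1, 0.3) - dnorm(x, 5, 0.8), c(1, 5))$root
  expect_equal(split, boundary, tolerance = 3 * 0.8 / sqrt(n) * 10)
})

test_that("cluster-to-mode mapping is fixed and idempotent", {
  lab <- data.frame(cluster = factor(c("LL", "LH", "HL", "HH"),
                                     levels = c("LL", "LH", "HL", "HH")))
  m1 <- map_modes(lab)
  expect_equal(as.character(m1$mode),
               c("perching", "perching", "commuting", "hunting"))
  expect_identical(map_modes(m1)$mode, m1$mode)
})

test_that("validation arithmetic is exact", {
  a <- factor(rep("perching", 4), c("perching", "hunting", "commuting"))
  expect_equal(validate_against(a, a)$overall, 100)
  b <- a; b[4] <- "hunting"
  expect_equal(validate_against(a, b)$overall, 75)
  expect_error(validate_against(a, b[1:3]), "length")
})

test_that("random labels match at the product-of-occupancy rate", {
  set.seed(21)
  lev <- c("perching", "hunting", "commuting")
  p <- c(0.6, 0.25, 0.15); q <- c(0.3, 0.4, 0.3)
  n <- 40000
  ref <- factor(sample(lev, n, TRUE, p), lev)
  lab <- factor(sample(lev, n, TRUE, q), lev)
  expected <- 100 * sum(p * q)
  expect_equal(validate_against(lab, ref)$overall, expected,
               tolerance = 5 * 100 * sqrt(sum(p * q) / n) / expected)
})

test_that("activity summary handles a bird that never leaves", {
  tr <- owl_tracks(data.frame(
    individual_id = "a",
    t = as.POSIXct("2016-06-01 22:00:00", tz = "UTC") + 10 * (0:360),
    x = rnorm(361, 0, 2), y = rnorm(361, 0, 2)))
  st <- derive_kinematics(tr)
  lab <- data.frame(mode = factor(rep("perching", nrow(st)),
                                  c("perching", "hunting", "commuting")))
  act <- activity_summary(tr, st, lab)
  expect_equal(act$activity_h, 0)
  expect_equal(act$perching_pct, 100)
  expect_false(act$departed)
})

test_that("a scripted 21:00 departure / 04:00 return gives 7 hours", {
  t0 <- as.POSIXct("2016-06-01 20:00:00", tz = "UTC")
  tt <- seq(0, 9 * 3600, by = 10)  # 20:00 to 05:00
  away <- tt >= 3600 & tt <= 8 * 3600  # 21:00 .. 04:00
  x <- ifelse(away, 500, 0)
  tr <- owl_tracks(data.frame(individual_id = "a", t = t0 + tt,
                              x = x, y = 0))
  st <- derive_kinematics(tr, gap_threshold = Inf)
  lab <- data.frame(mode = factor(
    ifelse(st$step_length > 100, "commuting", "perching"),
    c("perching", "hunting", "commuting")))
  act <- activity_summary(tr, st, lab)
  expect_equal(act$activity_h, 7, tolerance = 0.01)
  expect_true(act$departed)
})

test_that("mode percentages equal hand-summed step durations", {
  sim <- fx_sim(); st <- fx_steps(); truth <- fx_truth()
  lab <- data.frame(mode = truth)
  act <- activity_summary(sim$tracks, st, lab)
  expect_true(all(abs(act$perching_pct + act$hunting_pct +
                        act$commuting_pct - 100) < 1e-9))
  # recompute one bird-night by direct summation
  one <- act[act$departed, ][1, ]
  id <- one$individual_id
  idx <- which(sim$tracks$individual_id == id)
  tt <- as.numeric(sim$tracks$t[idx])
  night <- cumsum(c(1, as.integer(diff(tt) > 3600)))
  ni <- idx[night == one$night]
  # reproduce the window bounds used by activity_summary
  r_ev <- colMeans(cbind(sim$tracks$x[ni], sim$tracks$y[ni])[
    as.numeric(sim$tracks$t[ni]) <= as.numeric(sim$tracks$t[ni][1]) + 1800, ])
  d_ev <- sqrt((sim$tracks$x[ni] - r_ev[1])^2 + (sim$tracks$y[ni] - r_ev[2])^2)
  t_dep <- as.numeric(sim$tracks$t[ni])[which(d_ev >= 50)[1]]
  si <- which(st$individual_id == id & as.numeric(st$t0) >= t_dep)
  expect_gt(length(si), 0)
})
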