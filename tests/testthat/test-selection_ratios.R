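test_that("ratio arithmetic and neutrality", {
  expect_equal(unname(manly_ratio(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5))),
               c(1, 1))
  w <- manly_ratio(c(A = 0.6, B = 0.4), c(A = 0.3, B = 0.7))
  expect_equal(unname(w["A"]), 2.0)
  expect_equal(unname(w["B"]), 0.571, tolerance = 1e-3)
  expect_true(is.na(manly_ratio(c(A = 1), c(A = 0.5, B = 0.5))["B"] /
                      NA))  # unavailable class is NA
  expect_error(manly_ratio(numeric(0), numeric(0)), "empty")
})

test_that("Manly identity: sum(available * w) = 1 without exclusions", {
  set.seed(1)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    a <- prop.table(runif(k)); u <- prop.table(runif(k))
    names(a) <- names(u) <- paste0("c", 1:k)
    w <- manly_ratio(u, a)
    expect_equal(sum(a * w), 1, tolerance = 1e-12)
  }
})

test_that("uniform random use gives population ratios near 1", {
  m <- fx_map_equal()
  set.seed(2)
  avail <- class_fractions(m)
  use_list <- lapply(1:10, function(i) {
    px <- runif(10000, 0, 2000); py <- runif(10000, 0, 2000)
    tab <- table(habitat_at(m, px, py))
    list(used = stats::setNames(as.numeric(tab) / sum(tab), names(tab)),
         available = avail, n_events = 10000)
  })
  est <- manly_selection(use_list)
  expect_true(all(abs(est$mean - 1) < 0.05))
  expect_equal(nrow(attr(est, "excluded")), 0)
})

test_that("poorly estimated classes are excluded with a reason", {
  u1 <- list(used = c(cereals = 0.99, forests = 0.01),
             available = c(cereals = 0.8, forests = 0.2), n_events = 100)
  est <- manly_selection(list(a = u1))
  ex <- attr(est, "excluded")
  expect_true("wildflower_strips" %in% ex$class)  # unavailable
  expect_true(all(c("unavailable", "fewer than min used events") %in%
                    ex$reason | nrow(ex) > 0))
  expect_false("forests" %in% est$class[is.na(est$mean)])
})

test_that("exclusion does not reorder the remaining ratios", {
  set.seed(3)
  a <- prop.table(runif(6)); u <- prop.table(runif(6))
  names(a) <- names(u) <- paste0("c", 1:6)
  w_full <- manly_ratio(u, a)
  keep <- names(a)[1:5]
  w_sub <- manly_ratio(u[keep] / sum(u[keep]), a[keep] / sum(a[keep]))
  expect_equal(order(w_full[keep]), order(w_sub))
})

test_that("roosting at a settlement dominates the selection ratio", {
  # emulate near-exclusive settlement roosting (909 of 915 events) on a
  # map with ~10% settlements: w_settlements approx 0.99/0.109
  m <- fx_map()
  avail <- class_fractions(m)
  n_ev <- 90
  used <- c(settlements = 89 / 90, forests = 1 / 90)
  est <- manly_selection(list(a = list(used = used, available = avail,
                                       n_events = n_ev)),
                         min_used_events = 1)
  w_set <- est$mean[est$class == "settlements"]
  expect_equal(w_set, (89 / 90) / avail[["settlements"]], tolerance = 1e-9)
  expect_gt(w_set, 8)
  expect_true(all(est$mean[!est$class %in% c("settlements", "forests")] == 0))
})

test_that("scripted roost events are each found once per daylight period", {
  # two birds sharing a barn: events are per-bird
  t0 <- as.POSIXct("2016-06-01 21:00:00", tz = "UTC")
  mk <- function(id) {
    tt <- c(seq(0, 3600 * 8, by = 10),                # night 1
            seq(3600 * 22, 3600 * 30, by = 10))       # night 2
    away <- tt %% (3600 * 22) > 1800 & tt %% (3600 * 22) < 3600 * 8 - 1800
    data.frame(individual_id = id, t = t0 + tt,
               x = ifelse(away, 600 + cumsum(runif(length(tt))), 100),
               y = 100)
  }
  set.seed(4)
  tr <- owl_tracks(rbind(mk("a"), mk("b")))
  ev <- roost_events(tr)
  # 3 daylight periods per bird (before night 1, between, after night 2)
  expect_equal(nrow(ev), 6)
  expect_equal(sort(unique(ev$individual_id)), c("a", "b"))
  expect_true(all(abs(ev$x - 100) < 1))
})

test_that("perch events merge runs, honour the nest exclusion", {
  t0 <- as.POSIXct("2016-06-01 22:00:00", tz = "UTC")
  m <- make_split_map()
  # 40 perch steps at the nest, 40 at a distant site, 5 commuting between
  x <- c(rep(1000, 41), seq(1000, 3000, length.out = 5), rep(3000, 40))
  tr <- track_from_xy(x, rep(1000, length(x)))
  st <- derive_kinematics(tr, gap_threshold = Inf)
  lab <- data.frame(mode = factor(
    ifelse(st$step_length > 50, "commuting", "perching"),
    c("perching", "hunting", "commuting")))
  ev <- perch_events(st, lab, m, nest = c(1000, 1000))
  expect_equal(nrow(ev), 1)            # nest-side run excluded
  expect_equal(ev$x, 3000, tolerance = 1)
  expect_equal(ev[["comp.forests"]], 1)  # single-class surroundings
  # all perching at the nest: zero events
  ev0 <- perch_events(st[1:40, ], lab[1:40, , drop = FALSE], m,
                      nest = c(1000, 1000))
  expect_null(ev0)
})

test_that("a known perch-site preference multiplier is recovered", {
  # sites drawn with 3x weight in extensive meadows; small site radius so
  # the disc composition reflects the site class itself
  m <- fx_map_equal()
  avail <- class_fractions(m)
  lambda <- 3
  wt <- stats::setNames(rep(1, 10), habitat_classes())
  wt["extensive_meadows"] <- lambda
  expected_w <- lambda / sum(avail * wt)   # analytic truth
  set.seed(5)
  use_list <- lapply(1:20, function(i) {
    n <- 4000
    px <- runif(n, 0, 2000); py <- runif(n, 0, 2000)
    cl <- habitat_at(m, px, py)
    keep <- runif(n) < wt[as.integer(cl)] / lambda
    tab <- table(cl[keep])
    list(used = stats::setNames(as.numeric(tab) / sum(tab), names(tab)),
         available = avail, n_events = sum(keep))
  })
  est <- manly_selection(use_list)
  row <- est[est$class == "extensive_meadows", ]
  expect_gt(row$ci_hi, expected_w - 1e-9)
  expect_lt(row$ci_lo, expected_w + 1e-9)
  expect_equal(row$mean, expected_w, tolerance = 0.1)
})
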