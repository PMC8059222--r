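test_that("paths are typed by their nest endpoints", {
  nest <- c(0, 0)
  p1 <- make_path(c(10, 300, 800), c(0, 0, 0))       # starts at nest
  p2 <- make_path(c(800, 300, 60), c(0, 0, 0))       # ends near nest... not quite
  p3 <- make_path(c(500, 700, 900), c(500, 500, 500))
  typed <- classify_commuting(list(p1, p2, p3), nest, nest_radius = 50)
  expect_equal(attr(typed[[1]], "type"), "leave_nest")
  expect_equal(attr(typed[[2]], "type"), "within_habitat")  # 60 m > 50 m
  expect_equal(attr(typed[[3]], "type"), "within_habitat")
  # a loop out and back splits at the farthest point
  loop <- make_path(c(0, 400, 900, 400, 0), c(0, 0, 0, 0, 0))
  sp <- classify_commuting(list(loop), nest)
  expect_equal(vapply(sp, attr, "", "type"),
               c("leave_nest", "return_nest"))
})

test_that("a scripted night yields exact type counts", {
  nest <- c(0, 0)
  paths <- c(
    lapply(1:6, function(i) make_path(c(0, 200, 500), c(0, i, i))),
    lapply(1:6, function(i) make_path(c(500, 200, 0), c(i, i, 0))),
    lapply(1:9, function(i) make_path(c(300, 500, 700), c(i, i, i))))
  typed <- classify_commuting(paths, nest)
  tt <- table(vapply(typed, attr, "", "type"))
  expect_equal(as.integer(tt[c("leave_nest", "return_nest", "within_habitat")]),
               c(6L, 6L, 9L))
})

test_that("metrics match the 3-4-5 construction and direct recomputation", {
  straight <- make_path(c(0, 250, 500), c(0, 0, 0))
  m <- path_metrics(straight)
  expect_equal(m$deviation, 0)
  legs <- make_path(c(0, 300, 300), c(0, 0, 400))
  m <- path_metrics(legs)
  expect_equal(m$distance, 700)
  expect_equal(m$straight_line, 500)
  expect_equal(m$deviation, 200)
  set.seed(1)
  p <- make_path(cumsum(rnorm(12, 30, 10)), cumsum(rnorm(12, 0, 20)),
                 dt = 10)
  m <- path_metrics(p)
  expect_equal(m$distance, sum(sqrt(diff(p$x)^2 + diff(p$y)^2)))
  expect_equal(m$speed, m$distance / (110))
  expect_gte(m$deviation, 0)
})

test_that("randomized paths are rigid motions of the observed path", {
  set.seed(2)
  p <- make_path(cumsum(rnorm(8, 50, 20)), cumsum(rnorm(8, 10, 30)))
  alts <- randomize_path(p, map = NULL, n = 20, seed = 3)
  obs_sl <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  obs_ta <- diff(atan2(diff(p$y), diff(p$x)))
  for (a in alts) {
    sl <- sqrt(diff(a$x)^2 + diff(a$y)^2)
    ta <- diff(atan2(diff(a$y), diff(a$x)))
    expect_equal(sl, obs_sl, tolerance = 1e-11)
    expect_equal(sin(ta), sin(obs_ta), tolerance = 1e-9)
    expect_lt(sqrt((a$x[1] - p$x[1])^2 + (a$y[1] - p$y[1])^2), 1500 + 1e-9)
  }
})

test_that("relocated start points are uniform in the disc", {
  p <- make_path(c(0, 10), c(0, 0))
  starts <- t(vapply(randomize_path(p, n = 10000, seed = 4),
                     function(a) c(a$x[1], a$y[1]), numeric(2)))
  r2 <- rowSums(starts^2) / 1500^2     # should be U(0,1)
  bins <- cut(r2, seq(0, 1, by = 0.1))
  chi <- chisq.test(table(bins))
  expect_gt(chi$p.value, 0.01)
  ang <- atan2(starts[, 2], starts[, 1])
  expect_gt(chisq.test(table(cut(ang, seq(-pi, pi, length.out = 9))))$p.value,
            0.01)
})

test_that("corridor area matches the stadium formula and an MC oracle", {
  straight <- make_path(c(0, 400, 1000), c(0, 0, 0))
  expect_equal(corridor_area(straight, 20), 1000 * 40 + pi * 400,
               tolerance = 1e-9)
  # right-angle path: analytic formula against Monte-Carlo integration
  bend <- make_path(c(0, 300, 300), c(0, 0, 400))
  a <- suppressWarnings(corridor_area(bend, 20))
  mc <- corridor_area_mc(bend, 20, n = 4e5)
  expect_equal(a, mc, tolerance = 0.01)
  # closed-form check of the right-angle case
  expect_equal(a, 700 * 40 + pi * 400 - 400 * (tan(pi / 4) - pi / 4),
               tolerance = 1e-9)
})

test_that("buffer composition is exhaustive on a one-class map", {
  m <- generate_landscape(c(cereals = 1), region = c(0, 0, 2000, 2000),
                          patch_scale = 300, seed = 5)
  p <- make_path(c(500, 900, 1300), c(1000, 1050, 1000))
  comp <- buffer_composition(p, m)
  expect_equal(unname(comp["intensive_open"]), 1)
  expect_equal(sum(comp), 1)
})

test_that("buffer composition matches a fine point-in-corridor oracle", {
  m <- fx_map_equal()
  set.seed(6)
  p <- make_path(cumsum(c(600, rnorm(6, 60, 15))),
                 cumsum(c(900, rnorm(6, 20, 25))))
  comp <- buffer_composition(p, m, res = 2)
  # independent oracle: random points, exact habitat query
  n <- 60000
  bx <- range(p$x) + c(-25, 25); by <- range(p$y) + c(-25, 25)
  px <- runif(n, bx[1], bx[2]); py <- runif(n, by[1], by[2])
  inside <- owlmove:::dist_to_polyline(px, py, p$x, p$y) <= 20
  cl <- habitat_at(m, px[inside], py[inside], method = "exact")
  for (g in names(path_class_groups())) {
    frac <- mean(!is.na(cl) & cl %in% path_class_groups()[[g]])
    expect_equal(unname(comp[g]), frac, tolerance = 0.025)
  }
  expect_lte(sum(comp), 1 + 1e-12)
})

test_that("path choice sets keep observed plus n_alt congruent paths", {
  m <- fx_map_equal()
  set.seed(7)
  paths <- lapply(1:5, function(i)
    make_path(1000 + cumsum(rnorm(6, 50, 10)),
              1000 + cumsum(rnorm(6, 10, 20)),
              id = "a", pid = paste0("a.p", i), type = "within_habitat"))
  cs <- path_choice_sets(paths, m, n_alt = 20, seed = 8)
  expect_true(all(table(cs$stratum) == 21))
  expect_true(all(tapply(cs$is_case, cs$stratum, sum) == 1))
})

test_that("a forest-avoiding cohort yields a negative forest coefficient", {
  m <- fx_map()
  frac_forest <- function(p) buffer_composition(p, m)[["forests"]]
  set.seed(9)
  mk_bird <- function(id) {
    paths <- list(); tries <- 0
    while (length(paths) < 12 && tries < 400) {
      tries <- tries + 1
      x0 <- runif(1, 600, 3400); y0 <- runif(1, 600, 3400)
      th <- runif(1, 0, 2 * pi)
      len <- cumsum(abs(rnorm(6, 65, 10)))
      p <- make_path(x0 + len * cos(th), y0 + len * sin(th), id = id,
                     pid = paste0(id, ".p", length(paths) + 1),
                     type = "within_habitat")
      # acceptance probability falls with forest exposure (true beta < 0)
      if (runif(1) < exp(-3 * frac_forest(p))) paths <- c(paths, list(p))
    }
    paths
  }
  paths <- c(mk_bird("a"), mk_bird("b"), mk_bird("c"))
  cs <- path_choice_sets(paths, m, n_alt = 20, seed = 10)
  fit <- fit_pathsf(cs)
  est <- fit$population
  expect_lt(est$mean[est$class == "forests"], 0)
})

test_that("type contrasts recover imposed distance differences", {
  set.seed(11)
  rows <- list()
  for (b in 1:8) for (i in 1:12) {
    type <- sample(c("leave_nest", "return_nest", "within_habitat"), 1)
    base <- c(leave_nest = 500, return_nest = 700, within_habitat = 420)
    d <- rlnorm(1, log(base[[type]]), 0.3)
    rows[[length(rows) + 1]] <- data.frame(
      individual_id = paste0("b", b), path_id = paste0("b", b, ".", i),
      type = type, distance_m = d, straight_m = d * 0.95,
      deviation_m = d * 0.05, duration_s = d / 6.5, speed_mps = rnorm(1, 6.5, 0.4))
  }
  res <- compare_types(do.call(rbind, rows))
  ld <- res[res$response == "log_distance", ]
  expect_lt(ld$estimate[ld$contrast == "within - return"], 0)
  expect_lt(ld$p_value[ld$contrast == "within - return"], 0.01)
  # single-type input skips contrasts with a warning
  one <- do.call(rbind, rows)
  one$type <- "within_habitat"
  expect_warning(expect_null(compare_types(one)), "skipped")
})
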