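# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# default 4 x 4 km mosaic
fx_map <- function() fixture("map", function()
  generate_landscape(seed = 101))

# small 2 x 2 km mosaic, equal tenths
fx_map_equal <- function() fixture("map_equal", function()
  generate_landscape(rep(1 / 10, 10) |> stats::setNames(habitat_classes()),
                     patch_scale = 120, region = c(0, 0, 2000, 2000),
                     seed = 202))

# hand-built two-class map split at x = mid: cereals left, forests right
make_split_map <- function(region = c(0, 0, 4000, 2000), res = 5) {
  classes <- habitat_classes()
  w <- region[3] - region[1]; h <- region[4] - region[2]
  mid <- (region[1] + region[3]) / 2
  seeds <- cbind(x = c(region[1] + w / 4, region[3] - w / 4),
                 y = rep((region[2] + region[4]) / 2, 2))
  nx <- ceiling(w / res); ny <- ceiling(h / res)
  gx <- region[1] + (seq_len(nx) - 0.5) * (w / nx)
  rast_row <- ifelse(gx < mid, match("cereals", classes),
                     match("forests", classes))
  structure(list(region = as.numeric(region), classes = classes,
                 proportions = NULL, patch_scale = w / 2,
                 seeds = seeds,
                 seed_class = match(c("cereals", "forests"), classes),
                 strips = NULL, res = res, nx = nx, ny = ny,
                 raster = rep(rast_row, ny)),
            class = "habitat_map")
}

# simulated cohort with realistic kinematics but short nights (fast)
fx_sim <- function() fixture("sim", function() {
  cfg <- truth_config(night_start_h = 22, night_end_h = 2)
  simulate_tracks(fx_map(), cfg, n_birds = 4, n_nights = 2, seed = 303)
})

fx_steps <- function() fixture("steps", function()
  derive_kinematics(fx_sim()$tracks))

fx_truth <- function() fixture("truth", function()
  truth_step_modes(fx_sim(), fx_steps()))

fx_labels <- function() fixture("labels", function()
  embc_cluster(fx_steps()))

# straight constant-speed track for one bird
make_track <- function(n = 10, dt = 10, speed = 10, id = "a",
                       t0 = as.POSIXct("2016-06-01 22:00:00", tz = "UTC"),
                       x0 = 0, y0 = 0, heading = 0) {
  owl_tracks(data.frame(
    individual_id = id, t = t0 + dt * (seq_len(n) - 1),
    x = x0 + speed * dt * (seq_len(n) - 1) * cos(heading),
    y = y0 + speed * dt * (seq_len(n) - 1) * sin(heading)))
}

# track from explicit coordinates at a fixed interval
track_from_xy <- function(x, y, dt = 10, id = "a",
                          t0 = as.POSIXct("2016-06-01 22:00:00", tz = "UTC")) {
  owl_tracks(data.frame(individual_id = id,
                        t = t0 + dt * (seq_along(x) - 1), x = x, y = y))
}

# independent worst-offender speed-filter oracle: repeatedly delete the
# later fix of the fastest violating step until none remain
speed_filter_oracle <- function(t, x, y, max_speed = 15) {
  removed <- 0L
  repeat {
    v <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
    bad <- which(v > max_speed)
    if (length(bad) == 0) return(removed)
    k <- bad[which.max(v[bad])] + 1L
    t <- t[-k]; x <- x[-k]; y <- y[-k]
    removed <- removed + 1L
  }
}

# simple path constructor for path-selection tests
make_path <- function(x, y, dt = 10, id = "a", pid = "a.p1",
                      type = NULL) {
  d <- data.frame(t = dt * (seq_along(x) - 1), x = x, y = y)
  attr(d, "individual_id") <- id
  attr(d, "path_id") <- pid
  if (!is.null(type)) attr(d, "type") <- type
  class(d) <- c("commuting_path", "data.frame")
  d
}

# Monte-Carlo corridor area oracle
corridor_area_mc <- function(path, buffer, n = 2e5, seed = 1) {
  set.seed(seed)
  bx <- range(path$x) + c(-buffer, buffer)
  by <- range(path$y) + c(-buffer, buffer)
  px <- runif(n, bx[1], bx[2]); py <- runif(n, by[1], by[2])
  inside <- owlmove:::dist_to_polyline(px, py, path$x, path$y) <= buffer
  mean(inside) * diff(bx) * diff(by)
}
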