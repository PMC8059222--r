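## Commuting-path analyses: typing of commuting flights relative to the
## nest, straightness metrics, relocate-and-rotate null paths and the
## path-selection conditional logit on buffered-corridor composition.

#' Grouped habitat classes used by the path-selection analysis
#'
#' Corridor covariates pool the ten classes into five groups: intensive
#' open habitats (cereals, root vegetables, pastures, intensive
#' meadows), extensive open habitats (extensive meadows, wildflower
#' strips), forests, forest edges and roads.  Settlements are excluded.
#'
#' @return named list mapping group name to member classes.
#' @export
path_class_groups <- function() {
  list(intensive_open = c("cereals", "root_vegetables", "pastures",
                          "intensive_meadows"),
       extensive_open = c("extensive_meadows", "wildflower_strips"),
       forests = "forests", forest_edges = "forest_edges",
       roads = "roads")
}

#' Extract commuting paths from labelled steps
#'
#' A path is a maximal run of consecutive commuting-labelled steps
#' within one burst with at least `min_steps` steps.
#'
#' @param steps a `step_series`.
#' @param labels `behaviour_labels` aligned with `steps`.
#' @param min_steps minimum steps per path.
#' @return list of `commuting_path` data.frames (columns `t`, `x`, `y`;
#'   attributes `individual_id`, `path_id`).
#' @export
extract_commuting_paths <- function(steps, labels, min_steps = 3) {
  stopifnot(nrow(steps) == nrow(labels))
  n <- nrow(steps)
  comm <- !is.na(labels$mode) & labels$mode == "commuting"
  run <- cumsum(c(1, as.integer(diff(as.integer(comm)) != 0 |
                                  steps$burst_id[-1] != steps$burst_id[-n])))
  out <- list()
  for (rr in unique(run[comm])) {
    idx <- which(run == rr & comm)
    if (length(idx) < min_steps) next
    d <- data.frame(
      t = c(as.numeric(steps$t0[idx[1]]),
            as.numeric(steps$t0[idx]) + steps$dt[idx]),
      x = c(steps$x0[idx[1]], steps$x1[idx]),
      y = c(steps$y0[idx[1]], steps$y1[idx]))
    attr(d, "individual_id") <- steps$individual_id[idx[1]]
    attr(d, "path_id") <- sprintf("%s.p%d", steps$individual_id[idx[1]],
                                  length(out) + 1L)
    class(d) <- c("commuting_path", "data.frame")
    out[[length(out) + 1]] <- d
  }
  out
}

#' Classify commuting paths relative to the nest
#'
#' Paths starting within `nest_radius` of the nest are nest-leaving
#' flights, paths ending within it are nest-returning flights, and paths
#' doing neither are commutes within the habitat.  A path doing both is
#' split at its farthest point into a leaving and a returning leg.
#'
#' @param paths list of `commuting_path`s (one individual).
#' @param nest `c(x, y)`.
#' @param nest_radius metres.
#' @return list of paths with attribute `type` set to one of
#'   `"leave_nest"`, `"return_nest"`, `"within_habitat"`.
#' @export
classify_commuting <- function(paths, nest, nest_radius = 50) {
  out <- list()
  for (p in paths) {
    d0 <- sqrt((p$x[1] - nest[1])^2 + (p$y[1] - nest[2])^2)
    n <- nrow(p)
    d1 <- sqrt((p$x[n] - nest[1])^2 + (p$y[n] - nest[2])^2)
    starts <- d0 <= nest_radius; ends <- d1 <= nest_radius
    if (starts && ends && n >= 4) {
      dd <- sqrt((p$x - nest[1])^2 + (p$y - nest[2])^2)
      k <- which.max(dd)
      a <- p[1:k, , drop = FALSE]; b <- p[k:n, , drop = FALSE]
      for (nm in c("individual_id", "path_id")) {
        attr(a, nm) <- attr(p, nm); attr(b, nm) <- attr(p, nm)
      }
      attr(a, "path_id") <- paste0(attr(p, "path_id"), "a")
      attr(b, "path_id") <- paste0(attr(p, "path_id"), "b")
      attr(a, "type") <- "leave_nest"; attr(b, "type") <- "return_nest"
      class(a) <- class(b) <- class(p)
      out <- c(out, list(a, b))
    } else {
      attr(p, "type") <- if (starts) "leave_nest"
        else if (ends) "return_nest" else "within_habitat"
      out <- c(out, list(p))
    }
  }
  out
}

#' Straightness metrics of a path
#'
#' @param path a `commuting_path` (data.frame with `t`, `x`, `y`).
#' @return list: `distance` (sum of step lengths, m), `straight_line`
#'   (endpoint separation, m), `deviation` (`distance - straight_line`,
#'   m, non-negative), `duration` (s) and `speed`
#'   (`distance / duration`, m/s).
#' @export
path_metrics <- function(path) {
  n <- nrow(path)
  stopifnot(n >= 2)
  sl <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  dist <- sum(sl)
  straight <- sqrt((path$x[n] - path$x[1])^2 + (path$y[n] - path$y[1])^2)
  dur <- path$t[n] - path$t[1]
  list(distance = dist, straight_line = straight,
       deviation = dist - straight, duration = dur,
       speed = dist / dur)
}

#' Summary table of typed commuting paths
#'
#' @param paths list of typed paths (see [classify_commuting()]).
#' @return data.frame: `individual_id`, `path_id`, `type`, `distance_m`,
#'   `straight_m`, `deviation_m`, `duration_s`, `speed_mps`.
#' @export
commuting_summary <- function(paths) {
  rows <- lapply(paths, function(p) {
    m <- path_metrics(p)
    data.frame(individual_id = attr(p, "individual_id"),
               path_id = attr(p, "path_id"),
               type = attr(p, "type") %||% NA_character_,
               distance_m = m$distance, straight_m = m$straight_line,
               deviation_m = m$deviation, duration_s = m$duration,
               speed_mps = m$speed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate relocate-and-rotate null paths
#'
#' Each alternative rigidly moves the observed path: the starting point
#' is relocated uniformly within a disc of `radius` around the original
#' start and the whole path is rotated about the new start by a uniform
#' angle in [0, 2 pi).  Lengths and internal angles are preserved
#' exactly.  Alternatives with any vertex off-map are redrawn up to
#' `max_redraws` times; a failure is flagged via attribute `off_map`.
#'
#' @param path a `commuting_path`.
#' @param map a `habitat_map` (or `NULL` to skip the off-map check).
#' @param radius relocation radius (m).
#' @param n number of alternatives.
#' @param seed RNG seed.
#' @param max_redraws redraw cap per alternative.
#' @return list of `n` paths (data.frames `t`, `x`, `y`).
#' @export
randomize_path <- function(path, map = NULL, radius = 1500, n = 20,
                           seed = NULL, max_redraws = 100) {
  x0 <- path$x[1]; y0 <- path$y[1]
  rx <- path$x - x0; ry <- path$y - y0
  r <- if (!is.null(map)) map$region
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(max_redraws + 1)) {
        rr <- radius * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
        nx0 <- x0 + rr * cos(aa); ny0 <- y0 + rr * sin(aa)
        th <- runif(1, 0, 2 * pi)
        xs <- nx0 + rx * cos(th) - ry * sin(th)
        ys <- ny0 + rx * sin(th) + ry * cos(th)
        ok <- is.null(r) ||
          all(xs >= r[1] & xs <= r[3] & ys >= r[2] & ys <= r[4])
        if (ok || try > max_redraws) break
      }
      out <- data.frame(t = path$t, x = xs, y = ys)
      attr(out, "off_map") <- !ok
      class(out) <- c("commuting_path", "data.frame")
      out
    })
  })
}

## Minimum distance from points to a polyline, vectorized over points.
dist_to_polyline <- function(px, py, xs, ys) {
  dmin <- rep(Inf, length(px))
  for (j in seq_len(length(xs) - 1)) {
    ax <- xs[j]; ay <- ys[j]
    vx <- xs[j + 1] - ax; vy <- ys[j + 1] - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- (px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Corridor area of a buffered path
#'
#' Analytic area of the set of points within `buffer` of the polyline
#' (round joins): the stadium formula `2*b*L + pi*b^2` minus the
#' double-counted joint overlap `b^2 * (tan(tau/2) - tau/2)` at each
#' internal vertex with turning angle `tau`.  Exact for paths that do
#' not approach themselves within `2*buffer` and whose turns are not
#' extreme hairpins (a warning is issued when `tau` exceeds 150 degrees
#' or a segment is shorter than the joint overlap it must absorb).
#'
#' @param path a `commuting_path`.
#' @param buffer buffer half-width (m).
#' @return area (m^2).
#' @export
corridor_area <- function(path, buffer = 20) {
  sl <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  heading <- atan2(diff(path$y), diff(path$x))
  tau <- abs(wrap_angle(diff(heading)))
  if (any(tau > 150 / 180 * pi) ||
      (length(tau) > 0 && any(pmin(utils::head(sl, -1), sl[-1]) <
                                buffer * tan(pmax(tau, 0) / 2))))
    warning("sharp turns or very short segments; analytic corridor area is approximate")
  2 * buffer * sum(sl) + pi * buffer^2 -
    buffer^2 * sum(tan(tau / 2) - tau / 2)
}

#' Habitat composition of a buffered corridor
#'
#' Fraction of the 20-m corridor area falling in each grouped habitat
#' class, estimated by regular grid sampling of the corridor (points
#' within `buffer` of the polyline).  Fractions are relative to the
#' whole corridor, so they sum to at most 1; the gap is the excluded
#' settlement class plus any unmapped area.
#'
#' @param path a `commuting_path`.
#' @param map a `habitat_map`.
#' @param buffer buffer half-width (m).
#' @param groups class grouping (default [path_class_groups()]).
#' @param res sampling resolution (m).
#' @return named fractions over the groups.
#' @export
buffer_composition <- function(path, map, buffer = 20,
                               groups = path_class_groups(),
                               res = NULL) {
  res <- res %||% min(map$res, buffer / 4)
  bx <- range(path$x); by <- range(path$y)
  sx <- seq(bx[1] - buffer, bx[2] + buffer, by = res)
  sy <- seq(by[1] - buffer, by[2] + buffer, by = res)
  px <- rep(sx, times = length(sy)); py <- rep(sy, each = length(sx))
  keep <- dist_to_polyline(px, py, path$x, path$y) <= buffer
  cl <- habitat_at(map, px[keep], py[keep])
  n_tot <- sum(keep)
  vapply(groups, function(g) sum(!is.na(cl) & cl %in% g) / n_tot,
         numeric(1))
}

#' Build path-selection choice sets
#'
#' For every within-habitat commuting path, pairs the observed corridor
#' composition with that of `n_alt` relocate-and-rotate alternatives.
#' Strata containing an unplaceable alternative (still off-map after the
#' redraw cap) are dropped.
#'
#' @param paths list of typed paths; only `within_habitat` paths enter
#'   (nest-anchored flights are biased by the nest surroundings).
#' @param map a `habitat_map`.
#' @param n_alt alternatives per path.
#' @param radius relocation radius (m).
#' @param buffer corridor half-width (m).
#' @param seed RNG seed.
#' @return a `choice_sets`-style data.frame: `individual_id`, `stratum`,
#'   `burst_id`, `is_case` and one column per class group.
#' @export
path_choice_sets <- function(paths, map, n_alt = 20, radius = 1500,
                             buffer = 20, seed = NULL) {
  within <- Filter(function(p) identical(attr(p, "type"), "within_habitat"),
                   paths)
  if (length(within) == 0) stop("no within-habitat commuting paths")
  groups <- path_class_groups()
  with_seed(seed, {
    rows <- list()
    for (s in seq_along(within)) {
      p <- within[[s]]
      alts <- randomize_path(p, map, radius = radius, n = n_alt)
      if (any(vapply(alts, function(a) isTRUE(attr(a, "off_map")), TRUE)))
        next
      cc <- rbind(buffer_composition(p, map, buffer, groups),
                  t(vapply(alts, buffer_composition, numeric(length(groups)),
                           map = map, buffer = buffer, groups = groups)))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(individual_id = attr(p, "individual_id"),
                   stratum = s, burst_id = attr(p, "path_id"),
                   is_case = c(TRUE, rep(FALSE, n_alt))),
        as.data.frame(cc))
    }
    if (length(rows) == 0) stop("no usable path strata")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("choice_sets", "data.frame"))
  })
}

#' Fit the path-selection function per individual
#'
#' Conditional logistic regression of observed versus null corridors on
#' the grouped composition covariates, per bird, averaged to population
#' estimates as in the step-selection analysis.
#'
#' @param cs output of [path_choice_sets()].
#' @param ... passed to [fit_clogit()].
#' @return list with `fits` and `population` (a `selection_estimate`).
#' @export
fit_pathsf <- function(cs, ...) {
  groups <- names(path_class_groups())
  ids <- unique(cs$individual_id)
  fits <- list()
  for (id in ids) {
    d <- cs[cs$individual_id == id, , drop = FALSE]
    fits[[id]] <- fit_clogit(as.matrix(d[, groups]), d$is_case,
                             d$stratum, ...)
  }
  list(fits = fits,
       population = population_average(fits, covariates = groups,
                                       method = "pathsf"))
}

#' Compare commuting types on distance, deviation and speed
#'
#' Random-intercept linear models (bird identity as grouping factor) of
#' log distance, log deviation and speed on commuting type, reported as
#' the three pairwise contrasts (leave - within, leave - return,
#' within - return) with normal-approximation p-values.
#'
#' @param summary output of [commuting_summary()] across birds.
#' @param min_deviation floor applied before the log transform (m);
#'   perfectly straight two-fix paths have zero deviation.
#' @return data.frame of contrasts per response, or `NULL` for a
#'   response observed in fewer than two types.
#' @export
compare_types <- function(summary, min_deviation = 0.01) {
  d <- summary[!is.na(summary$type), , drop = FALSE]
  d$type <- factor(d$type,
                   levels = c("within_habitat", "leave_nest", "return_nest"))
  if (nlevels(droplevels(d$type)) < 2) {
    warning("fewer than two commuting types present; contrasts skipped")
    return(NULL)
  }
  responses <- list(
    log_distance = log(d$distance_m),
    log_deviation = log(pmax(d$deviation_m, min_deviation)),
    speed = d$speed_mps)
  out <- list()
  for (rn in names(responses)) {
    d$y <- responses[[rn]]
    fit <- lme4::lmer(y ~ type + (1 | individual_id), data = d)
    b <- lme4::fixef(fit); V <- as.matrix(stats::vcov(fit))
    ## contrasts in terms of the fixed effects (reference = within)
    cons <- list("leave - within" = c(0, 1, 0),
                 "leave - return" = c(0, 1, -1),
                 "within - return" = c(0, 0, -1))
    for (cn in names(cons)) {
      k <- cons[[cn]][seq_along(b)]
      est <- sum(k * b); se <- sqrt(drop(t(k) %*% V %*% k))
      out[[length(out) + 1]] <- data.frame(
        response = rn, contrast = cn, estimate = est, se = se,
        z = est / se, p_value = 2 * stats::pnorm(-abs(est / se)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
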