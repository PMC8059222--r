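#' Manly selection ratios for one individual
#'
#' The third-order selection ratio of a habitat class is its used
#' fraction divided by its available fraction; `w > 1` indicates
#' preference.  Classes unavailable to the individual get `NA`.
#'
#' @param used,available named fraction vectors over the same classes,
#'   each summing to 1 over included classes.
#' @return named ratio vector.
#' @examples
#' manly_ratio(c(A = 0.6, B = 0.4), c(A = 0.3, B = 0.7))
#' @export
manly_ratio <- function(used, available) {
  if (length(used) == 0) stop("empty use set")
  cls <- union(names(used), names(available))
  u <- stats::setNames(numeric(length(cls)), cls); u[names(used)] <- used
  a <- stats::setNames(numeric(length(cls)), cls)
  a[names(available)] <- available
  w <- ifelse(a > 0, u / a, NA_real_)
  stats::setNames(w, cls)
}

## Population mean and normal-approximation 95% CI across individuals of
## a birds x classes coefficient matrix (NAs = bird excluded for class).
population_estimate <- function(coefs, method) {
  cls <- colnames(coefs)
  n <- colSums(!is.na(coefs))
  mean_ <- colMeans(coefs, na.rm = TRUE)
  se <- apply(coefs, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  out <- data.frame(class = cls, mean = mean_, se = se,
                    ci_lo = mean_ - 1.96 * se, ci_hi = mean_ + 1.96 * se,
                    n_individuals = as.integer(n), row.names = NULL)
  structure(out, method = method,
            class = c("selection_estimate", "data.frame"))
}

#' Cohort-level Manly selection analysis
#'
#' Computes per-individual selection ratios and averages them across the
#' cohort to population estimates with normal-approximation 95%
#' confidence intervals.  Poorly estimated classes are excluded and
#' reported: a class is dropped when it is available to no individual or
#' when fewer than `min_used_events` use events exist across the cohort.
#'
#' @param use_list list with one element per individual, each a list with
#'   named fraction vectors `used` and `available`, and `n_events` (used
#'   to translate fractions into cohort event counts).
#' @param min_used_events cohort-wide minimum used events per class.
#' @return a `selection_estimate` data.frame (class, mean, se, ci_lo,
#'   ci_hi, n_individuals) with attribute `excluded` (class, reason).
#' @export
manly_selection <- function(use_list, min_used_events = 5) {
  if (length(use_list) == 0) stop("empty use set")
  cls <- habitat_classes()
  W <- matrix(NA_real_, length(use_list), length(cls),
              dimnames = list(names(use_list) %||% seq_along(use_list), cls))
  counts <- avail_any <- stats::setNames(numeric(length(cls)), cls)
  for (i in seq_along(use_list)) {
    u <- use_list[[i]]
    w <- manly_ratio(u$used, u$available)
    W[i, names(w)] <- w
    uu <- stats::setNames(numeric(length(cls)), cls)
    uu[names(u$used)] <- u$used
    counts <- counts + uu * (u$n_events %||% 1)
    aa <- stats::setNames(numeric(length(cls)), cls)
    aa[names(u$available)] <- u$available
    avail_any <- avail_any + (aa > 0)
  }
  reason <- character(0); excl <- character(0)
  for (cl in cls) {
    if (avail_any[cl] == 0) { excl <- c(excl, cl); reason <- c(reason, "unavailable") }
    else if (counts[cl] < min_used_events) {
      excl <- c(excl, cl); reason <- c(reason, "fewer than min used events")
    }
  }
  W[, excl] <- NA
  keep <- setdiff(cls, excl)
  out <- population_estimate(W[, keep, drop = FALSE], method = "manly")
  attr(out, "excluded") <- data.frame(class = excl, reason = reason)
  attr(out, "per_individual") <- W
  out
}

#' @export
print.selection_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<selection_estimate> method = %s\n", attr(x, "method")))
  print.data.frame(x, digits = digits)
  ex <- attr(x, "excluded")
  if (!is.null(ex) && nrow(ex) > 0)
    cat("excluded:", paste(ex$class, collapse = ", "), "\n")
  invisible(x)
}

#' Home-range use versus nest-centred availability
#'
#' Third-order design for home-range placement: the available habitat is
#' the composition of the 1.5-km disc around the nest (the mapped
#' landscape unit) and the used habitat is the home-range composition.
#'
#' @param hr a `home_range` for the individual.
#' @param map a `habitat_map`.
#' @param nest `c(x, y)` nest coordinates (m).
#' @param radius availability radius around the nest (m).
#' @return list with `used`, `available`, `n_events` (number of fixes).
#' @export
home_range_use <- function(hr, map, nest, radius = 1500) {
  used <- composition(hr, map)
  avail <- disc_composition(map, nest[1], nest[2], radius, warn = FALSE)
  list(used = used, available = avail, n_events = hr$n_fixes)
}

#' Identify daylight roosting events
#'
#' Nights are blocks of fixes separated by more than `night_gap`.  Each
#' daylight period pairs the post-dawn window (last `window` seconds) of
#' one night with the pre-dusk window (first `window` seconds) of the
#' next; the first pre-dusk and last post-dawn windows stand alone.  A
#' roosting event is recorded at the centroid of the period's fixes when
#' their displacement stays below `max_displacement` (a bird resting at
#' one site through the day).
#'
#' @param tracks an `owl_tracks` object.
#' @param night_gap gap splitting nights (s).
#' @param window margin window recorded around each night (s).
#' @param max_displacement stationarity threshold (m).
#' @return data.frame: `individual_id`, `day`, `x`, `y`, `n_fixes`.
#' @export
roost_events <- function(tracks, night_gap = 3600, window = 1800,
                         max_displacement = 25) {
  res <- list()
  for (id in unique(tracks$individual_id)) {
    idx <- which(tracks$individual_id == id)
    tt <- as.numeric(tracks$t[idx])
    night <- cumsum(c(1, as.integer(diff(tt) > night_gap)))
    nn <- max(night)
    for (d in 0:nn) {  # daylight period d sits between nights d and d+1
      pts <- integer(0)
      if (d >= 1) {   # post-dawn of night d
        ni <- idx[night == d]; tn <- tt[night == d]
        pts <- c(pts, ni[tn >= tn[length(tn)] - window])
      }
      if (d < nn) {   # pre-dusk of night d+1
        ni <- idx[night == d + 1]; tn <- tt[night == d + 1]
        pts <- c(pts, ni[tn <= tn[1] + window])
      }
      if (length(pts) < 2) next
      px <- tracks$x[pts]; py <- tracks$y[pts]
      disp <- max(sqrt((px - mean(px))^2 + (py - mean(py))^2))
      if (disp < max_displacement)
        res[[length(res) + 1]] <- data.frame(
          individual_id = id, day = d, x = mean(px), y = mean(py),
          n_fixes = length(pts))
    }
  }
  out <- do.call(rbind, res) %||%
    data.frame(individual_id = character(0), day = integer(0),
               x = numeric(0), y = numeric(0), n_fixes = integer(0))
  rownames(out) <- NULL
  out
}

#' Roosting-site selection input for one individual
#'
#' Used composition is the class frequency of the individual's roost
#' sites (class at the event centroid); availability is the home-range
#' composition.
#'
#' @param events [roost_events()] rows of one individual.
#' @param map a `habitat_map`.
#' @param hr the individual's `home_range`.
#' @return list with `used`, `available`, `n_events`.
#' @export
roost_use <- function(events, map, hr) {
  if (nrow(events) == 0) stop("no roost events for this individual")
  cl <- habitat_at(map, events$x, events$y)
  tab <- table(cl)
  used <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  list(used = used, available = composition(hr, map),
       n_events = nrow(events))
}

#' Identify nocturnal perching events
#'
#' Merges runs of consecutive perching-labelled steps within a burst
#' into events, keeps events lasting at least `min_duration`, drops
#' events within `nest_exclusion_radius` of the nest (the nest site is
#' not a habitat choice), and attaches the habitat composition of a disc
#' of `site_radius` around each event site.
#'
#' @param steps a `step_series` for one individual.
#' @param labels `behaviour_labels` aligned with `steps`.
#' @param map a `habitat_map`.
#' @param nest `c(x, y)` nest coordinates.
#' @param nest_exclusion_radius,min_duration,site_radius metres, seconds,
#'   metres.
#' @return data.frame with one row per event: site coordinates,
#'   `duration`, `n_steps`, and one composition column per class
#'   (`comp.<class>`).
#' @export
perch_events <- function(steps, labels, map, nest,
                         nest_exclusion_radius = 50, min_duration = 30,
                         site_radius = 100) {
  stopifnot(nrow(steps) == nrow(labels))
  perch <- labels$mode == "perching" & !is.na(labels$mode)
  run <- cumsum(c(1, as.integer(diff(as.integer(perch)) != 0 |
                                  steps$burst_id[-1] != steps$burst_id[-nrow(steps)])))
  res <- list()
  for (rr in unique(run[perch])) {
    idx <- which(run == rr & perch)
    dur <- sum(steps$dt[idx])
    if (dur < min_duration) next
    sx <- mean(steps$x1[idx]); sy <- mean(steps$y1[idx])
    if (sqrt((sx - nest[1])^2 + (sy - nest[2])^2) < nest_exclusion_radius)
      next
    comp <- disc_composition(map, sx, sy, site_radius, warn = FALSE)
    full <- stats::setNames(numeric(length(habitat_classes())),
                            habitat_classes())
    full[names(comp)] <- comp
    res[[length(res) + 1]] <- cbind(
      data.frame(individual_id = steps$individual_id[idx[1]],
                 x = sx, y = sy, duration = dur, n_steps = length(idx)),
      as.data.frame(as.list(stats::setNames(full, paste0("comp.", names(full))))))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out
}

#' Perching-site selection input for one individual
#'
#' Used composition is the mean of the per-event disc compositions
#' (equal event weighting by default, duration weighting optional);
#' availability is the home-range composition.
#'
#' @param events [perch_events()] output for one individual (or `NULL`).
#' @param hr the individual's `home_range`.
#' @param map a `habitat_map`.
#' @param weight `"event"` (default) or `"duration"`.
#' @return list with `used`, `available`, `n_events`, or `NULL` when the
#'   bird has no perch events (the bird is then excluded upstream).
#' @export
perch_use <- function(events, hr, map, weight = c("event", "duration")) {
  weight <- match.arg(weight)
  if (is.null(events) || nrow(events) == 0) return(NULL)
  comp_cols <- grep("^comp\\.", names(events), value = TRUE)
  M <- as.matrix(events[, comp_cols])
  w <- if (weight == "duration") events$duration else rep(1, nrow(events))
  used <- colSums(M * w) / sum(w)
  names(used) <- sub("^comp\\.", "", names(used))
  list(used = used, available = composition(hr, map),
       n_events = nrow(events))
}
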