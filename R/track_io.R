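#' Construct a track collection
#'
#' Bundles timestamped GPS fixes of one or more individuals with per-bird
#' metadata.  Coordinates are planar metres in a projected frame;
#' longitude/latitude input must be projected beforehand.
#'
#' @param fixes data.frame with columns `individual_id`, `t` (POSIXct,
#'   UTC), `x`, `y` (m).
#' @param meta optional data.frame with one row per individual: columns
#'   `individual_id` and any of `sex` ("M"/"F"), `age_class`
#'   ("yearling"/"older"), `nest_x`, `nest_y`, `year`, `brood_id`,
#'   `deploy_date`.
#' @return an `owl_tracks` data.frame (fixes sorted by individual and
#'   time) with the metadata attached as attribute `meta`.
#' @export
owl_tracks <- function(fixes, meta = NULL) {
  need <- c("individual_id", "t", "x", "y")
  if (!all(need %in% names(fixes)))
    stop("missing column(s): ", paste(setdiff(need, names(fixes)), collapse = ", "))
  fixes <- fixes[, need]
  fixes$individual_id <- as.character(fixes$individual_id)
  if (!inherits(fixes$t, "POSIXct")) stop("t must be POSIXct")
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y)))
    stop("coordinates must be finite")
  o <- order(fixes$individual_id, fixes$t)
  if (is.unsorted(o)) {
    warning("fixes were not sorted by individual and time; sorting")
    fixes <- fixes[o, ]
  }
  dup <- duplicated(fixes[, c("individual_id", "t")])
  if (any(dup)) stop("duplicate (individual_id, timestamp) fixes")
  rownames(fixes) <- NULL
  if (!is.null(meta)) {
    meta$individual_id <- as.character(meta$individual_id)
    if (anyDuplicated(meta$individual_id)) stop("duplicate metadata rows")
  }
  structure(fixes, meta = meta, class = c("owl_tracks", "data.frame"))
}

#' @export
print.owl_tracks <- function(x, ...) {
  cat(sprintf("<owl_tracks> %d fixes, %d individuals\n",
              nrow(x), length(unique(x$individual_id))))
  invisible(x)
}

track_meta <- function(tracks) attr(tracks, "meta")

nest_of <- function(tracks, id) {
  meta <- track_meta(tracks)
  if (is.null(meta) || !all(c("nest_x", "nest_y") %in% names(meta)))
    stop("track metadata with nest coordinates required")
  i <- match(id, meta$individual_id)
  if (is.na(i)) stop("no metadata for individual ", id)
  c(meta$nest_x[i], meta$nest_y[i])
}

#' Read tracks from CSV
#'
#' Expects tracking-database-style columns `individual_id`, `timestamp` (ISO-8601,
#' UTC, or numeric seconds since epoch), `x`, `y` (projected metres).
#' Rows are sorted by time within individual (with a warning when input
#' was unsorted); duplicate (individual, timestamp) rows are an error.
#'
#' @param path CSV path.
#' @param meta_path optional per-bird metadata CSV.
#' @return an [owl_tracks()] object.
#' @export
read_tracks <- function(path, meta_path = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("individual_id", "timestamp", "x", "y")
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)), collapse = ", "))
  if (is.numeric(raw$timestamp)) {
    t <- as.POSIXct(raw$timestamp, origin = "1970-01-01", tz = "UTC")
  } else {
    t <- rep(as.POSIXct(NA), nrow(raw))
    for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
      miss <- is.na(t)
      if (!any(miss)) break
      t[miss] <- as.POSIXct(strptime(raw$timestamp[miss], fmt, tz = "UTC"))
    }
  }
  if (anyNA(t)) stop("unparseable timestamp(s), e.g. ",
                     raw$timestamp[which(is.na(t))[1]])
  meta <- if (!is.null(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE, comment.char = "#")
  owl_tracks(data.frame(individual_id = raw$individual_id, t = t,
                        x = raw$x, y = raw$y), meta = meta)
}

#' Write tracks (and optionally labels) to CSV
#'
#' @param tracks an `owl_tracks` object.
#' @param path output CSV path.
#' @param meta_path optional path for the metadata CSV.
#' @export
write_tracks <- function(tracks, path, meta_path = NULL) {
  out <- data.frame(
    individual_id = tracks$individual_id,
    timestamp = format(tracks$t, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
    x = tracks$x, y = tracks$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- track_meta(tracks)
  if (!is.null(meta_path) && !is.null(meta))
    utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter aberrant positions
#'
#' Applies the standard pre-analysis position filter: fixes outside the
#' study region are dropped, then any step faster than `max_speed` is
#' resolved by removing its later fix, recomputing speeds, until no
#' violation remains (a single forward pass against the last retained fix
#' reaches this fixpoint).  The filter is idempotent.
#'
#' @param tracks an `owl_tracks` object.
#' @param max_speed speed threshold in m/s (default 15, above the fastest
#'   plausible flight).
#' @param region optional `c(xmin, ymin, xmax, ymax)` or a `habitat_map`.
#' @return list with elements `tracks` (filtered) and `n_removed`.
#' @export
filter_positions <- function(tracks, max_speed = 15, region = NULL) {
  stopifnot(max_speed > 0)
  if (inherits(region, "habitat_map")) region <- region$region
  keep <- rep(TRUE, nrow(tracks))
  if (!is.null(region)) {
    keep <- tracks$x >= region[1] & tracks$x <= region[3] &
      tracks$y >= region[2] & tracks$y <= region[4]
  }
  df <- tracks[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  parts <- split(seq_len(nrow(df)), df$individual_id)
  drop <- logical(nrow(df))
  for (id in names(parts)) {
    idx <- parts[[id]]
    if (length(idx) < 2) next
    tt <- as.numeric(df$t[idx]); xx <- df$x[idx]; yy <- df$y[idx]
    last <- 1L
    for (i in 2:length(idx)) {
      v <- sqrt((xx[i] - xx[last])^2 + (yy[i] - yy[last])^2) /
        (tt[i] - tt[last])
      if (is.finite(v) && v > max_speed) drop[idx[i]] <- TRUE else last <- i
    }
    if (all(drop[idx[-1]]))
      warning("individual ", id, ": track nearly empty after speed filter")
  }
  n_removed <- n_removed + sum(drop)
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  empty <- setdiff(unique(tracks$individual_id), unique(out$individual_id))
  if (length(empty) > 0)
    warning("individual(s) with no fixes left after filtering: ",
            paste(empty, collapse = ", "))
  list(tracks = structure(out, meta = track_meta(tracks),
                          class = c("owl_tracks", "data.frame")),
       n_removed = n_removed)
}

#' Derive per-step kinematics and bursts
#'
#' Splits each individual's fixes into bursts wherever the sampling gap
#' exceeds `gap_threshold`, then computes step length, duration, speed,
#' absolute heading and signed turning angle (angle from the previous to
#' the current displacement, in (-pi, pi]; undefined for the first step
#' of a burst) for each consecutive fix pair within a burst.
#'
#' @param tracks an `owl_tracks` object (or data.frame with the same
#'   columns).
#' @param gap_threshold burst-splitting gap in seconds (default 30, i.e.
#'   more than two missed fixes at 10-s sampling).
#' @return a `step_series` data.frame with one row per step: columns
#'   `individual_id`, `burst_id`, `fix0`, `fix1` (row indices of the step
#'   endpoints in `tracks`), `t0`, `dt`, `x0`, `y0`, `x1`, `y1`,
#'   `step_length`, `speed`, `heading`, `turning_angle`.
#' @export
derive_kinematics <- function(tracks, gap_threshold = 30) {
  stopifnot(nrow(tracks) >= 2)
  res <- vector("list", 0L)
  parts <- split(seq_len(nrow(tracks)), tracks$individual_id)
  for (id in names(parts)) {
    idx <- parts[[id]]
    if (length(idx) < 2) next
    tt <- as.numeric(tracks$t[idx]); xx <- tracks$x[idx]; yy <- tracks$y[idx]
    dt <- diff(tt)
    burst <- cumsum(c(1, as.integer(dt > gap_threshold)))
    i0 <- seq_len(length(idx) - 1L); i1 <- i0 + 1L
    same <- burst[i0] == burst[i1]
    if (!any(same)) next
    dx <- xx[i1] - xx[i0]; dy <- yy[i1] - yy[i0]
    sl <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx)
    ta <- rep(NA_real_, length(i0))
    prev_same <- c(FALSE, same[-length(same)]) & same
    ta[prev_same] <- wrap_angle(heading[prev_same] -
                                  heading[which(prev_same) - 1L])
    d <- data.frame(
      individual_id = id,
      burst_id = paste0(id, ".b", burst[i0]),
      fix0 = idx[i0], fix1 = idx[i1],
      t0 = tracks$t[idx][i0], dt = dt,
      x0 = xx[i0], y0 = yy[i0], x1 = xx[i1], y1 = yy[i1],
      step_length = sl, speed = sl / dt,
      heading = heading, turning_angle = ta)[same, , drop = FALSE]
    res[[id]] <- d
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, gap_threshold = gap_threshold,
            class = c("step_series", "data.frame"))
}
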