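## Behavioural annotation of steps by expectation-maximization binary
## clustering on (speed, |turning angle|): a 4-component bivariate
## Gaussian mixture initialized at the per-variable medians, with the
## components labelled Low/High on each axis after convergence and the
## four binary regions merged into three behavioural modes.

log_dmvnorm2 <- function(X, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det
  dx <- sweep(X, 2, mu)
  q <- dx[, 1]^2 * inv[1, 1] + 2 * dx[, 1] * dx[, 2] * inv[1, 2] +
    dx[, 2]^2 * inv[2, 2]
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

## Equal-likelihood boundary between the Low and High component groups
## along one axis of the fitted mixture (falls back to the midpoint of
## the closest group means when the densities do not cross).
group_boundary <- function(mu, sd, w, low, high) {
  lo <- max(mu[low]); hi <- min(mu[high])
  if (hi <= lo) return(mean(c(lo, hi)))
  f <- function(x)
    log(sum(w[low] * stats::dnorm(x, mu[low], sd[low])) + 1e-300) -
    log(sum(w[high] * stats::dnorm(x, mu[high], sd[high])) + 1e-300)
  tryCatch(stats::uniroot(f, c(lo, hi))$root,
           error = function(e) mean(c(lo, hi)))
}

cov_reg <- function(X, w, ridge) {
  mu <- colSums(X * w) / sum(w)
  dx <- sweep(X, 2, mu)
  S <- crossprod(dx * w, dx) / sum(w)
  S <- S + diag(ridge, 2)
  list(mu = mu, S = S)
}

#' Cluster movement steps into four binary speed-turn regions
#'
#' Fits a 4-component bivariate Gaussian mixture to (speed, |turning
#' angle|) by expectation-maximization.  Components are initialized from
#' the 2 x 2 partition of the data at the per-variable medians, and after
#' convergence are labelled `LL`, `LH`, `HL`, `HH` (Low/High speed x
#' Low/High absolute turn) by ordering the component means on each axis.
#' The log-likelihood is non-decreasing across iterations and the fit is
#' deterministic for a given input (the `seed` argument is accepted for
#' interface symmetry; the median initialization uses no randomness).
#'
#' Steps with undefined turning angle (first step of a burst) are
#' assigned afterwards from the marginal speed likelihood.
#'
#' @param steps a `step_series` from [derive_kinematics()].
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param seed unused (deterministic algorithm); kept for call symmetry.
#' @return a `behaviour_labels` data.frame aligned row-for-row with
#'   `steps`: columns `individual_id`, `cluster` (LL/LH/HL/HH) and
#'   `mode` (filled by [map_modes()], which is applied automatically);
#'   mixture parameters and axis delimiters in attribute `params`.
#' @export
embc_cluster <- function(steps, max_iter = 200, tol = 1e-6, seed = NULL) {
  sp <- steps$speed
  at <- abs(steps$turning_angle)
  ok <- is.finite(sp) & is.finite(at)
  if (sum(ok) < 4) stop("need at least 4 steps with defined turning angle")
  X <- cbind(sp[ok], at[ok])
  for (j in 1:2) {
    v <- c("speed", "absolute turning angle")[j]
    if (stats::sd(X[, j]) < 1e-10)
      stop("degenerate variance in ", v, "; cannot cluster")
  }
  ridge <- 1e-8 * max(apply(X, 2, stats::var))

  ## median-split initialization
  med <- apply(X, 2, stats::median)
  grp <- 1L + (X[, 1] > med[1]) * 2L + (X[, 2] > med[2])
  comp <- vector("list", 4); wts <- numeric(4)
  for (k in 1:4) {
    idx <- grp == k
    if (sum(idx) < 3) idx <- rep(TRUE, nrow(X))  # fallback: global init
    comp[[k]] <- cov_reg(X[idx, , drop = FALSE], rep(1, sum(idx)), ridge)
    wts[k] <- max(mean(grp == k), 1e-3)
  }
  wts <- wts / sum(wts)

  loglik <- -Inf; trace <- numeric(0)
  R <- NULL
  for (it in seq_len(max_iter)) {
    lp <- vapply(1:4, function(k)
      log(wts[k]) + log_dmvnorm2(X, comp[[k]]$mu, comp[[k]]$S),
      numeric(nrow(X)))
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    R <- exp(lp - lse)
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol * (1 + abs(ll))) {
      loglik <- ll
      break
    }
    loglik <- ll
    for (k in 1:4) {
      wk <- pmax(R[, k], 1e-12)
      comp[[k]] <- cov_reg(X, wk, ridge)
    }
    wts <- pmax(colMeans(R), 1e-8); wts <- wts / sum(wts)
  }

  ## binary labelling: two lowest mean speeds -> L speed; within each
  ## speed pair the lower mean |turn| -> L turn
  mu_sp <- vapply(comp, function(c) c$mu[1], 0)
  mu_at <- vapply(comp, function(c) c$mu[2], 0)
  sp_rank <- order(mu_sp)
  lowsp <- sp_rank[1:2]; highsp <- sp_rank[3:4]
  lab <- character(4)
  lab[lowsp[order(mu_at[lowsp])]] <- c("LL", "LH")
  lab[highsp[order(mu_at[highsp])]] <- c("HL", "HH")
  sd_sp <- vapply(comp, function(c) sqrt(c$S[1, 1]), 0)
  sd_at <- vapply(comp, function(c) sqrt(c$S[2, 2]), 0)
  speed_split <- group_boundary(mu_sp, sd_sp, wts, lowsp, highsp)
  lowat <- which(lab %in% c("LL", "HL")); highat <- which(lab %in% c("LH", "HH"))
  turn_split <- group_boundary(mu_at, sd_at, wts, lowat, highat)

  cl <- rep(NA_integer_, nrow(steps))
  cl[ok] <- max.col(R)
  ## speed-only assignment for first-of-burst steps
  miss <- which(!ok & is.finite(sp))
  if (length(miss) > 0) {
    lp1 <- vapply(1:4, function(k)
      log(wts[k]) + stats::dnorm(sp[miss], comp[[k]]$mu[1],
                                 sqrt(comp[[k]]$S[1, 1]), log = TRUE),
      numeric(length(miss)))
    cl[miss] <- max.col(matrix(lp1, nrow = length(miss)))
  }

  labels <- data.frame(
    individual_id = steps$individual_id,
    cluster = factor(lab[cl], levels = c("LL", "LH", "HL", "HH")),
    mode = factor(NA, levels = c("perching", "hunting", "commuting")))
  params <- list(
    weights = stats::setNames(wts, lab),
    means = stats::setNames(lapply(comp, `[[`, "mu"), lab),
    covariances = stats::setNames(lapply(comp, `[[`, "S"), lab),
    delimiters = c(speed = speed_split, turn = turn_split),
    loglik = trace, n_iter = length(trace),
    converged = length(trace) < max_iter)
  out <- structure(labels, params = params,
                   class = c("behaviour_labels", "data.frame"))
  map_modes(out)
}

#' Map binary clusters to behavioural modes
#'
#' Both low-speed regions are stationary behaviour (perching: GPS noise
#' gives low speed with arbitrary turning angles), high speed with low
#' turn is directed flight (commuting) and high speed with high turn is
#' tortuous flight (hunting).  Applying the mapping twice is a no-op.
#'
#' @param labels a `behaviour_labels` data.frame with `cluster` set.
#' @return the same object with `mode` filled.
#' @export
map_modes <- function(labels) {
  stopifnot(!is.null(labels$cluster))
  m <- c(LL = "perching", LH = "perching", HL = "commuting", HH = "hunting")
  labels$mode <- factor(m[as.character(labels$cluster)],
                        levels = c("perching", "hunting", "commuting"))
  labels
}

#' Annotate steps with behavioural modes
#'
#' Convenience wrapper running [embc_cluster()] per individual, falling
#' back to a population-pooled fit for birds with fewer than `min_steps`
#' steps (a per-bird mixture is poorly identified on short tracks).
#'
#' @param steps a `step_series`.
#' @param per_individual fit one mixture per bird (default) or one pooled
#'   mixture for everyone.
#' @param min_steps pooled-fallback threshold.
#' @param ... passed to [embc_cluster()].
#' @return a `behaviour_labels` data.frame aligned with `steps`.
#' @export
annotate_behaviour <- function(steps, per_individual = TRUE,
                               min_steps = 500, ...) {
  if (!per_individual) return(embc_cluster(steps, ...))
  ids <- unique(steps$individual_id)
  counts <- table(steps$individual_id)
  small <- names(counts)[counts < min_steps]
  out <- data.frame(
    individual_id = steps$individual_id,
    cluster = factor(NA, levels = c("LL", "LH", "HL", "HH")),
    mode = factor(NA, levels = c("perching", "hunting", "commuting")))
  pooled <- NULL
  if (length(small) > 0) pooled <- embc_cluster(steps, ...)
  for (id in ids) {
    idx <- steps$individual_id == id
    if (id %in% small) {
      out$cluster[idx] <- pooled$cluster[idx]
      out$mode[idx] <- pooled$mode[idx]
    } else {
      fit <- embc_cluster(steps[idx, , drop = FALSE], ...)
      out$cluster[idx] <- fit$cluster
      out$mode[idx] <- fit$mode
    }
  }
  structure(out, class = c("behaviour_labels", "data.frame"))
}

#' Compare two behavioural labelings
#'
#' @param labels,reference `behaviour_labels` (or factors/characters of
#'   modes) over the same steps.
#' @return a `validation_report` list: `overall` match percentage,
#'   `per_mode` recall percentages of the reference modes, and the
#'   `confusion` table (reference in rows).
#' @export
validate_against <- function(labels, reference) {
  a <- if (is.data.frame(labels)) labels$mode else labels
  b <- if (is.data.frame(reference)) reference$mode else reference
  if (length(a) != length(b)) stop("label sets differ in length")
  lev <- c("perching", "hunting", "commuting")
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  conf <- table(reference = b, labels = a)
  per_mode <- 100 * diag(conf) / pmax(rowSums(conf), 1)
  structure(list(overall = 100 * mean(a == b), per_mode = per_mode,
                 confusion = conf),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("overall match: %.1f%%\n", x$overall))
  print(round(x$per_mode, 1))
  invisible(x)
}

#' Nightly activity period and time budget per mode
#'
#' A night is a block of fixes separated from the next by more than
#' `night_gap` seconds (the daylight roosting gap).  The activity period
#' runs from the first fix at least `roost_radius` from the evening roost
#' (centroid of the night's first `roost_window` seconds of fixes) to the
#' last fix at least `roost_radius` from the morning roost (centroid of
#' the last `roost_window` seconds).  Mode percentages are step-duration
#' weighted over the activity period.
#'
#' @param tracks an `owl_tracks` object.
#' @param steps the `step_series` derived from `tracks`.
#' @param labels `behaviour_labels` aligned with `steps`.
#' @param roost_radius departure/return distance threshold (m).
#' @param night_gap minimum day gap splitting nights (s).
#' @param roost_window roost-averaging window (s).
#' @return data.frame with one row per bird-night: `individual_id`,
#'   `night`, `activity_h`, `perching_pct`, `hunting_pct`,
#'   `commuting_pct`, `departed`.
#' @export
activity_summary <- function(tracks, steps, labels, roost_radius = 50,
                             night_gap = 3600, roost_window = 1800) {
  stopifnot(nrow(steps) == nrow(labels))
  res <- list()
  for (id in unique(tracks$individual_id)) {
    idx <- which(tracks$individual_id == id)
    tt <- as.numeric(tracks$t[idx])
    night <- cumsum(c(1, as.integer(diff(tt) > night_gap)))
    for (ng in unique(night)) {
      ni <- idx[night == ng]
      if (length(ni) < 2) next
      tn <- as.numeric(tracks$t[ni])
      ev <- tn <= tn[1] + roost_window
      mo <- tn >= tn[length(tn)] - roost_window
      r_ev <- c(mean(tracks$x[ni][ev]), mean(tracks$y[ni][ev]))
      r_mo <- c(mean(tracks$x[ni][mo]), mean(tracks$y[ni][mo]))
      d_ev <- sqrt((tracks$x[ni] - r_ev[1])^2 + (tracks$y[ni] - r_ev[2])^2)
      d_mo <- sqrt((tracks$x[ni] - r_mo[1])^2 + (tracks$y[ni] - r_mo[2])^2)
      dep <- which(d_ev >= roost_radius)[1]
      ret <- if (any(d_mo >= roost_radius)) max(which(d_mo >= roost_radius)) else NA
      row <- data.frame(individual_id = id, night = ng, activity_h = 0,
                        perching_pct = 100, hunting_pct = 0,
                        commuting_pct = 0, departed = FALSE)
      if (!is.na(dep) && !is.na(ret) && ret > dep) {
        t_dep <- tn[dep]; t_ret <- tn[ret]
        row$activity_h <- (t_ret - t_dep) / 3600
        row$departed <- TRUE
        si <- which(steps$individual_id == id &
                      as.numeric(steps$t0) >= t_dep &
                      as.numeric(steps$t0) + steps$dt <= t_ret)
        if (length(si) > 0) {
          dur <- tapply(steps$dt[si], labels$mode[si], sum)
          dur[is.na(dur)] <- 0
          pct <- 100 * dur / sum(dur)
          row$perching_pct <- pct[["perching"]]
          row$hunting_pct <- pct[["hunting"]]
          row$commuting_pct <- pct[["commuting"]]
        }
      }
      res[[length(res) + 1]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
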