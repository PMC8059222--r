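#' Thin steps to a coarser time interval
#'
#' Rebuilds a step series on fixes retained at multiples of `interval`
#' from the start of each run, recomputing step lengths, speeds and
#' turning angles on the thinned series.  When behaviour `labels` are
#' supplied, only runs of consecutive steps of the requested `mode`
#' (within one burst) are used — the standard pre-processing for the
#' hunting step-selection analysis, where 30-s steps are long enough to
#' be weakly autocorrelated.
#'
#' @param steps a `step_series`.
#' @param interval target interval (s); equal to the fix interval this is
#'   the identity.
#' @param labels optional `behaviour_labels` aligned with `steps`.
#' @param mode behavioural mode selecting the runs when `labels` given.
#' @return a `step_series` data.frame on the thinned fixes, with
#'   `burst_id` identifying the (mode) run.
#' @export
thin_to_interval <- function(steps, interval = 30, labels = NULL,
                             mode = "hunting") {
  n <- nrow(steps)
  in_mode <- if (is.null(labels)) rep(TRUE, n) else
    (!is.na(labels$mode) & labels$mode == mode)
  brk <- c(1, as.integer(diff(as.integer(in_mode)) != 0 |
                           steps$burst_id[-1] != steps$burst_id[-n]))
  run <- cumsum(brk)
  res <- list()
  for (rr in unique(run[in_mode])) {
    idx <- which(run == rr & in_mode)
    ## fixes of the run: start of first step plus end of every step
    tt <- c(as.numeric(steps$t0[idx[1]]),
            as.numeric(steps$t0[idx]) + steps$dt[idx])
    xx <- c(steps$x0[idx[1]], steps$x1[idx])
    yy <- c(steps$y0[idx[1]], steps$y1[idx])
    rel <- tt - tt[1]
    keep <- which(!duplicated(floor(rel / interval + 1e-9)))
    keep <- keep[abs(rel[keep] %% interval) < 1e-6]
    if (length(keep) < 2) next
    tt <- tt[keep]; xx <- xx[keep]; yy <- yy[keep]
    dx <- diff(xx); dy <- diff(yy); dt <- diff(tt)
    sl <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx)
    ta <- c(NA, wrap_angle(diff(heading)))
    res[[length(res) + 1]] <- data.frame(
      individual_id = steps$individual_id[idx[1]],
      burst_id = paste0(steps$burst_id[idx[1]], ".r", rr),
      t0 = as.POSIXct(tt[-length(tt)], origin = "1970-01-01", tz = "UTC"),
      dt = dt, x0 = xx[-length(xx)], y0 = yy[-length(yy)],
      x1 = xx[-1], y1 = yy[-1], step_length = sl, speed = sl / dt,
      heading = heading, turning_angle = ta)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  structure(out, class = c("step_series", "data.frame"))
}

#' Pooled empirical movement distributions
#'
#' Step-length and turning-angle pools over the whole population's
#' observed (thinned) steps, from which alternative steps are resampled.
#'
#' @param steps a (thinned) `step_series`.
#' @return list with vectors `step_length` and `turn`.
#' @export
movement_pools <- function(steps) {
  ok <- is.finite(steps$turning_angle)
  list(step_length = steps$step_length,
       turn = steps$turning_angle[ok])
}

#' Sample alternative step endpoints for one stratum
#'
#' Draws `K` (step length, turning angle) pairs independently and
#' uniformly with replacement from the empirical pools and places the
#' endpoints from the step start using the observed previous heading.
#' Endpoints falling outside the mapped region are redrawn (up to
#' `max_redraws` rounds); any still outside are flagged.
#'
#' @param x0,y0 step start.
#' @param prev_heading heading of the previous observed step (rad).
#' @param pools [movement_pools()].
#' @param K number of alternatives.
#' @param map optional `habitat_map` used for the off-map redraws.
#' @param max_redraws redraw rounds.
#' @return data.frame `x`, `y`, `step_length`, `turn`, `off_map`.
#' @export
sample_alternatives <- function(x0, y0, prev_heading, pools, K = 100,
                                map = NULL, max_redraws = 100) {
  if (length(pools$step_length) == 0 || length(pools$turn) == 0)
    stop("empty movement pool")
  draw <- function(n) {
    len <- pools$step_length[sample.int(length(pools$step_length), n,
                                        replace = TRUE)]
    trn <- pools$turn[sample.int(length(pools$turn), n, replace = TRUE)]
    th <- prev_heading + trn
    data.frame(x = x0 + len * cos(th), y = y0 + len * sin(th),
               step_length = len, turn = trn)
  }
  out <- draw(K)
  out$off_map <- FALSE
  if (!is.null(map)) {
    r <- map$region
    for (i in seq_len(max_redraws)) {
      bad <- out$x < r[1] | out$x > r[3] | out$y < r[2] | out$y > r[4]
      if (!any(bad)) break
      out[bad, c("x", "y", "step_length", "turn")] <- draw(sum(bad))
    }
    out$off_map <- out$x < r[1] | out$x > r[3] | out$y < r[2] | out$y > r[4]
  }
  out
}

#' Build step-selection choice sets
#'
#' Pairs every observed (thinned) step having a defined previous heading
#' with `K` alternative steps resampled from the population pools, and
#' extracts the habitat class and movement covariates (step length, log
#' step length, cosine of the turning angle) for case and controls.
#' Strata whose case endpoint is off-map, or with alternatives that
#' could not be placed on the map, are dropped.
#'
#' @param thinned a thinned `step_series` (see [thin_to_interval()]).
#' @param map a `habitat_map`.
#' @param pools [movement_pools()]; defaults to pools built from
#'   `thinned` itself (the population's observed distribution).
#' @param K alternatives per observed step.
#' @param seed RNG seed.
#' @return a `choice_sets` data.frame: `individual_id`, `stratum`,
#'   `burst_id`, `is_case`, `x`, `y`, `habitat`, `step_length`,
#'   `log_step_length`, `cos_turning_angle`.
#' @export
ssf_choice_sets <- function(thinned, map, pools = NULL, K = 100,
                            seed = NULL) {
  pools <- pools %||% movement_pools(thinned)
  obs <- thinned[is.finite(thinned$turning_angle), , drop = FALSE]
  if (nrow(obs) == 0) stop("no steps with defined previous heading")
  with_seed(seed, {
    S <- nrow(obs)
    prev_heading <- obs$heading - obs$turning_angle
    np <- length(pools$step_length); nt <- length(pools$turn)
    if (np == 0 || nt == 0) stop("empty movement pool")
    len <- matrix(pools$step_length[sample.int(np, S * K, TRUE)], S, K)
    trn <- matrix(pools$turn[sample.int(nt, S * K, TRUE)], S, K)
    th <- prev_heading + trn
    ax <- obs$x0 + len * cos(th)
    ay <- obs$y0 + len * sin(th)
    r <- map$region
    for (i in seq_len(100)) {
      bad <- ax < r[1] | ax > r[3] | ay < r[2] | ay > r[4]
      if (!any(bad)) break
      nb <- sum(bad)
      l2 <- pools$step_length[sample.int(np, nb, TRUE)]
      t2 <- pools$turn[sample.int(nt, nb, TRUE)]
      h2 <- rep(prev_heading, times = K)[bad] + t2
      len[bad] <- l2; trn[bad] <- t2
      ax[bad] <- rep(obs$x0, times = K)[bad] + l2 * cos(h2)
      ay[bad] <- rep(obs$y0, times = K)[bad] + l2 * sin(h2)
    }
    still_bad <- rowSums(ax < r[1] | ax > r[3] | ay < r[2] | ay > r[4]) > 0

    case <- data.frame(
      individual_id = obs$individual_id,
      stratum = seq_len(S), burst_id = obs$burst_id, is_case = TRUE,
      x = obs$x1, y = obs$y1,
      step_length = obs$step_length,
      cos_turning_angle = cos(obs$turning_angle))
    ctrl <- data.frame(
      individual_id = rep(obs$individual_id, K),
      stratum = rep(seq_len(S), K),
      burst_id = rep(obs$burst_id, K), is_case = FALSE,
      x = as.vector(ax), y = as.vector(ay),
      step_length = as.vector(len),
      cos_turning_angle = cos(as.vector(trn)))
    cs <- rbind(case, ctrl)
    cs$log_step_length <- log(pmax(cs$step_length, 1e-9))
    cs$habitat <- habitat_at(map, cs$x, cs$y)
    drop_strata <- unique(c(which(is.na(cs$habitat[cs$is_case])),
                            which(still_bad)))
    cs <- cs[!(cs$stratum %in% drop_strata), , drop = FALSE]
    cs <- cs[order(cs$stratum, -cs$is_case), ]
    rownames(cs) <- NULL
    structure(cs, class = c("choice_sets", "data.frame"))
  })
}

#' Conditional logistic regression by Newton-Raphson
#'
#' Maximizes the stratified conditional likelihood
#' `sum_s [x_case . beta - log sum_j exp(x_j . beta)]` over choice sets
#' with exactly one case per stratum.  Covariates that are constant
#' within every stratum carry no information and are dropped with a
#' reason; monotone-likelihood separation is flagged as non-convergence.
#' Standard errors come from the inverse observed information.
#'
#' @param X numeric covariate matrix (rows = case + control steps).
#' @param is_case logical case indicator.
#' @param stratum stratum identifier.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return a `clogit_fit` list: `coefficients`, `se`, `loglik`,
#'   `null_loglik`, `converged`, `n_strata`, `dropped`, `iterations`.
#' @export
fit_clogit <- function(X, is_case, stratum, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  st <- factor(stratum)
  if (!all(tapply(is_case, st, sum) == 1))
    stop("each stratum must contain exactly one case")
  ## centre within stratum; drop covariates constant within all strata
  Xc <- X - apply(X, 2, function(v) ave(v, st))
  keep <- apply(abs(Xc), 2, max) > 1e-10
  dropped <- colnames(X)[!keep]
  Xk <- Xc[, keep, drop = FALSE]
  d <- ncol(Xk)
  S <- nlevels(st)
  null_ll <- -sum(log(tabulate(st)))
  if (d == 0)
    return(structure(list(coefficients = numeric(0), se = numeric(0),
                          loglik = null_ll, null_loglik = null_ll,
                          converged = TRUE, n_strata = S,
                          dropped = dropped, iterations = 0L),
                     class = "clogit_fit"))
  beta <- numeric(d)
  ll_of <- function(beta) {
    eta <- drop(Xk %*% beta)
    m <- ave(eta, st, FUN = max)
    lse <- log(ave(exp(eta - m), st, FUN = sum)) + m
    p <- exp(eta - lse)
    list(ll = sum((eta - lse)[is_case]), p = p)
  }
  cur <- ll_of(beta)
  converged <- FALSE
  it <- 0L
  Vinv <- NULL
  for (it in seq_len(max_iter)) {
    p <- cur$p
    g <- drop(crossprod(Xk, is_case - p))
    M <- rowsum(Xk * p, st)
    H <- crossprod(Xk, Xk * p) - crossprod(M)
    if (sqrt(sum(g^2)) < tol * (1 + abs(cur$ll))) { converged <- TRUE; break }
    step <- tryCatch(solve(H + diag(1e-10, d), g), error = function(e) g)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new <- ll_of(cand)
      if (new$ll >= cur$ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (new$ll <= cur$ll + 1e-12 && lam < 1e-6) break
    beta <- beta + lam * step
    cur <- new
  }
  p <- cur$p
  M <- rowsum(Xk * p, st)
  H <- crossprod(Xk, Xk * p) - crossprod(M)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, d))
  separated <- any(abs(beta) > 15)
  if (separated) converged <- FALSE
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(Xk)),
    se = stats::setNames(se, colnames(Xk)),
    loglik = cur$ll, null_loglik = null_ll, converged = converged,
    n_strata = S, dropped = dropped, iterations = it,
    separated = separated), class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("<clogit_fit> %d strata, loglik %.2f%s\n", x$n_strata,
              x$loglik, if (x$converged) "" else " (NOT converged)"))
  print(round(cbind(beta = x$coefficients, se = x$se), 4))
  invisible(x)
}

## Design matrix for the integrated SSF: one-hot habitat indicators over
## the modelled classes (reference and excluded classes all-zero) plus
## the three movement covariates.
ssf_design <- function(cs, reference_class = "cereals",
                       exclude_classes = c("roads", "settlements"),
                       movement = TRUE) {
  cls <- setdiff(habitat_classes(), c(reference_class, exclude_classes))
  X <- vapply(cls, function(cl) as.numeric(cs$habitat == cl),
              numeric(nrow(cs)))
  colnames(X) <- cls
  if (movement)
    X <- cbind(X, step_length = cs$step_length,
               log_step_length = cs$log_step_length,
               cos_turning_angle = cs$cos_turning_angle)
  X
}

#' Fit the integrated step-selection function per individual
#'
#' Runs a conditional logistic regression for every bird on its choice
#' sets, with one-hot habitat indicators (default reference: cereals,
#' the commonest class; roads and settlements excluded as too rare to
#' support estimation) plus step length, log step length and cosine of
#' the turning angle, then averages the per-bird habitat coefficients
#' into population estimates.  Non-converged (separated) birds are
#' excluded from the averaging, per class.
#'
#' @param cs a `choice_sets` data.frame.
#' @param reference_class habitat reference level.
#' @param exclude_classes classes omitted from the model.
#' @param movement include the movement covariates (integrated SSF).
#' @param min_case_events classes with fewer observed (case) steps than
#'   this for a bird are poorly estimated (the likelihood is maximized
#'   at minus infinity when a class is never used) and are refitted out
#'   of that bird's model; their coefficient is reported missing.
#' @param ... passed to [fit_clogit()].
#' @return list with `fits` (per-bird `clogit_fit`s) and `population`
#'   (a `selection_estimate`).
#' @export
fit_ssf <- function(cs, reference_class = "cereals",
                    exclude_classes = c("roads", "settlements"),
                    movement = TRUE, min_case_events = 1, ...) {
  ids <- unique(cs$individual_id)
  cls <- setdiff(habitat_classes(), c(reference_class, exclude_classes))
  fits <- list()
  coefs <- matrix(NA_real_, length(ids), length(cls),
                  dimnames = list(ids, cls))
  for (id in ids) {
    d <- cs[cs$individual_id == id, , drop = FALSE]
    case_counts <- table(factor(d$habitat[d$is_case], levels = cls))
    rare <- names(case_counts)[case_counts < min_case_events]
    X <- ssf_design(d, reference_class, c(exclude_classes, rare), movement)
    fit <- fit_clogit(X, d$is_case, d$stratum, ...)
    fit$rare_dropped <- rare
    fits[[id]] <- fit
    if (fit$converged) {
      b <- fit$coefficients[intersect(names(fit$coefficients), cls)]
      coefs[id, names(b)] <- b
    }
  }
  list(fits = fits, population = population_estimate(coefs, method = "ssf"))
}

#' Average per-individual selection fits into population estimates
#'
#' Unweighted mean with a normal-approximation 95% confidence interval
#' across converged individuals, per covariate.
#'
#' @param fits list of `clogit_fit`s.
#' @param covariates covariate names to average (default: union).
#' @param method label stored on the result.
#' @return a `selection_estimate` data.frame.
#' @export
population_average <- function(fits, covariates = NULL, method = "ssf") {
  fits <- Filter(function(f) f$converged, fits)
  if (length(fits) == 0) stop("no converged fits")
  covariates <- covariates %||%
    unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  coefs <- t(vapply(fits, function(f) {
    out <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
    b <- f$coefficients[intersect(names(f$coefficients), covariates)]
    out[names(b)] <- b
    out
  }, numeric(length(covariates))))
  population_estimate(coefs, method = method)
}
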