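#' Bray-Curtis dissimilarity of selection coefficient profiles
#'
#' Bray-Curtis requires non-negative data, while conditional-logit
#' selection coefficients are log-odds and can be negative; by default
#' coefficients are exponentiated into relative selection strengths
#' before the dissimilarity `sum|x - y| / sum(x + y)` is computed.  A
#' min-shift transform is available as an alternative.
#'
#' @param M numeric matrix, individuals in rows.
#' @param transform `"exp"` (default), `"shift"` (subtract the matrix
#'   minimum) or `"none"` (data already non-negative).
#' @return a `dist` object with values in [0, 1].
#' @export
bray_curtis <- function(M, transform = c("exp", "shift", "none")) {
  transform <- match.arg(transform)
  M <- as.matrix(M)
  if (anyNA(M)) stop("coefficient matrix contains missing values")
  M <- switch(transform, exp = exp(M), shift = M - min(M), none = M)
  if (any(M < 0)) stop("negative values; choose a transform")
  n <- nrow(M)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    num <- colSums(abs(t(M[-seq_len(i), , drop = FALSE]) - M[i, ]))
    den <- colSums(t(M[-seq_len(i), , drop = FALSE]) + M[i, ])
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- ifelse(den > 0, num / den, 0)
  }
  rownames(d) <- colnames(d) <- rownames(M)
  stats::as.dist(d)
}

## Monotone (isotonic) regression of configuration distances on the
## rank order of the dissimilarities.
monotone_fit <- function(delta, dv) {
  ord <- order(delta)
  fit <- stats::isoreg(dv[ord])$yf
  out <- numeric(length(dv))
  out[ord] <- fit
  out
}

kruskal_stress <- function(dv, dhat) sqrt(sum((dv - dhat)^2) / sum(dv^2))

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS: alternates monotone regression of configuration
#' distances on the dissimilarity ranks with a Guttman-transform
#' (stress-majorization) configuration update, enforcing a
#' non-increasing stress-1 sequence by step halving.  The best of
#' `n_starts` starts is kept; the first start is the classical metric
#' scaling solution, the rest are random.
#'
#' @param d a `dist` of dissimilarities.
#' @param k embedding dimension (default 3).
#' @param n_starts random starts (plus the metric-scaling start).
#' @param max_iter,tol iteration cap and stress-change tolerance.
#' @param seed RNG seed.
#' @return an `nmds_result`: `points` (n x k), `stress` (Kruskal
#'   stress-1), `stress_trace` of the winning start, `converged`.
#' @export
nmds <- function(d, k = 3, n_starts = 20, max_iter = 200, tol = 1e-6,
                 seed = NULL) {
  delta <- as.vector(d)
  n <- attr(d, "Size")
  if (k >= n - 1) stop("k must be smaller than n - 1")
  pair <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  config_dist <- function(X)
    sqrt(rowSums((X[pair[, 1], , drop = FALSE] -
                    X[pair[, 2], , drop = FALSE])^2))
  guttman <- function(X, dv, dhat) {
    r <- ifelse(dv > 1e-12, dhat / dv, 0)
    B <- matrix(0, n, n)
    B[cbind(pair[, 1], pair[, 2])] <- -r
    B[cbind(pair[, 2], pair[, 1])] <- -r
    diag(B) <- -rowSums(B)
    (B %*% X) / n
  }
  run_start <- function(X) {
    X <- scale(X, scale = FALSE)
    dv <- config_dist(X)
    if (all(dv < 1e-12)) return(list(X = X, stress = Inf, trace = Inf))
    dhat <- monotone_fit(delta, dv)
    s <- kruskal_stress(dv, dhat)
    trace <- s
    for (it in seq_len(max_iter)) {
      Xn <- guttman(X, dv, dhat)
      for (half in 0:20) {
        dvn <- config_dist(Xn)
        dhn <- monotone_fit(delta, dvn)
        sn <- kruskal_stress(dvn, dhn)
        if (sn <= s + 1e-15) break
        Xn <- (Xn + X) / 2
      }
      if (sn > s) { sn <- s; dvn <- dv; dhn <- dhat; Xn <- X }
      conv <- (s - sn) < tol
      X <- Xn; dv <- dvn; dhat <- dhn; s <- sn
      trace <- c(trace, s)
      if (conv) break
    }
    list(X = X, stress = s, trace = trace)
  }
  with_seed(seed, {
    best <- NULL
    init0 <- suppressWarnings(
      stats::cmdscale(d, k = k, add = TRUE)$points)
    if (ncol(init0) < k)
      init0 <- cbind(init0, matrix(stats::rnorm(n * (k - ncol(init0)),
                                                sd = 1e-3), n))
    starts <- c(list(init0),
                replicate(max(0, n_starts - 1),
                          matrix(stats::runif(n * k, -1, 1) * max(delta), n),
                          simplify = FALSE))
    for (X0 in starts) {
      res <- run_start(X0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    structure(list(points = best$X, stress = best$stress,
                   stress_trace = best$trace,
                   converged = length(best$trace) < max_iter + 1,
                   k = k, n = n), class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> %d points in %d dimensions, stress-1 = %.4f\n",
              x$n, x$k, x$stress))
  invisible(x)
}

#' Permutation test of variables against an ordination
#'
#' For a continuous variable, `r2` is the coefficient of determination
#' of the variable regressed on the configuration axes, and the
#' direction is the unit vector of the regression coefficients.  For a
#' categorical variable, `r2` is the between-group share of the total
#' sum of squares of the coordinates.  Significance is assessed by
#' permuting the variable across individuals:
#' `p = (1 + #(perm r2 >= observed)) / (1 + n_perm)`.
#'
#' @param config an `nmds_result` or an n x k coordinate matrix.
#' @param variables data.frame of per-individual variables (numeric =
#'   continuous, factor/character = categorical).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame `variable`, `r2`, `p`, `n_perm`; directions of
#'   continuous variables in attribute `directions`.
#' @export
envfit_permutation <- function(config, variables, n_perm = 10000,
                               seed = NULL) {
  X <- if (inherits(config, "nmds_result")) config$points else as.matrix(config)
  X <- scale(X, scale = FALSE)
  n <- nrow(X)
  r2_cont <- function(v) {
    f <- stats::lm.fit(cbind(1, X), v)
    1 - sum(f$residuals^2) / sum((v - mean(v))^2)
  }
  r2_cat <- function(v) {
    tot <- sum(X^2)
    wit <- 0
    for (g in unique(v)) {
      Xi <- X[v == g, , drop = FALSE]
      wit <- wit + sum(scale(Xi, scale = FALSE)^2)
    }
    (tot - wit) / tot
  }
  with_seed(seed, {
    out <- list(); dirs <- list()
    for (nm in names(variables)) {
      v <- variables[[nm]]
      if (is.numeric(v)) {
        if (stats::sd(v) < 1e-12) stop("constant variable: ", nm)
        stat <- r2_cont
        cf <- stats::lm.fit(cbind(1, X), v)$coefficients[-1]
        dirs[[nm]] <- cf / sqrt(sum(cf^2))
      } else {
        v <- factor(v)
        if (nlevels(droplevels(v)) < 2) stop("constant variable: ", nm)
        stat <- r2_cat
      }
      obs <- stat(if (is.numeric(v)) v else v)
      ge <- 0L
      for (i in seq_len(n_perm)) {
        if (stat(v[sample.int(n)]) >= obs - 1e-12) ge <- ge + 1L
      }
      out[[nm]] <- data.frame(variable = nm, r2 = obs,
                              p = (1 + ge) / (1 + n_perm),
                              n_perm = n_perm)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "directions") <- dirs
    res
  })
}

#' Ordinate per-individual hunting selection coefficients
#'
#' Convenience pipeline: drop rarely estimable classes (wildflower
#' strips by default), build the Bray-Curtis dissimilarity of the
#' transformed coefficients, run a 3-D NMDS and, when explanatory
#' variables are given, a permutation envelope fit.
#'
#' @param coefs individuals x classes coefficient matrix.
#' @param variables optional per-individual data.frame (same row order).
#' @param drop_classes classes removed before ordination.
#' @param transform passed to [bray_curtis()].
#' @param k,n_perm,seed see [nmds()] and [envfit_permutation()].
#' @param ... passed to [nmds()].
#' @return list with `nmds`, `fit` (or `NULL`) and the `dissimilarity`.
#' @export
ordinate_selection <- function(coefs, variables = NULL,
                               drop_classes = "wildflower_strips",
                               transform = "exp", k = 3, n_perm = 10000,
                               seed = NULL, ...) {
  M <- as.matrix(coefs)
  M <- M[, setdiff(colnames(M), drop_classes), drop = FALSE]
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  d <- bray_curtis(M, transform = transform)
  ord <- nmds(d, k = k, seed = seed, ...)
  fit <- NULL
  if (!is.null(variables)) {
    fit <- envfit_permutation(ord, variables[keep, , drop = FALSE],
                              n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else seed + 1)
  }
  list(nmds = ord, fit = fit, dissimilarity = d)
}
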