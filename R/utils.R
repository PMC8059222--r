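#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG state seeded with `seed`
## (NULL seed = use current stream).  Restores the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible 32-bit sub-seed from a global seed and a label.
derive_seed <- function(seed, label) {
  u <- as.numeric(utf8ToInt(label))
  h <- sum(u * seq_along(u) * 2654435) %% 2147483587
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483587)
}

## Wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

## Wrapped-Cauchy draws centred on `mu` with mean resultant length `rho`.
## rho = 0 is circular uniform, rho -> 1 concentrates at mu.
rwrapped_cauchy <- function(n, mu = 0, rho = 0.5) {
  stopifnot(rho >= 0, rho < 1)
  u <- runif(n, -0.5, 0.5)
  if (rho == 0) return(wrap_angle(mu + 2 * pi * u))
  theta <- 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * u))
  wrap_angle(mu + theta)
}

#' Area of a disc
#'
#' Convenience helper used when defining landscape availability around a
#' nest site (e.g. the mapped disc of radius 1.5 km).
#'
#' @param radius disc radius.
#' @return area in squared units of `radius`.
#' @examples
#' disc_area(1.5)  # km^2 mapped around a nest when radius is in km
#' @export
disc_area <- function(radius) pi * radius^2

#' Relative tag load
#'
#' Mass of a biologging device expressed as a percentage of body mass,
#' the standard welfare criterion for tag deployment.
#'
#' @param tag_mass_g tag mass in grams.
#' @param body_mass_g bird body mass in grams.
#' @return percentage (0-100).
#' @examples
#' tag_load_pct(12, 251)
#' @export
tag_load_pct <- function(tag_mass_g, body_mass_g) {
  stopifnot(tag_mass_g > 0, body_mass_g > 0)
  100 * tag_mass_g / body_mass_g
}
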