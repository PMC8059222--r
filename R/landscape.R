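#' The ten farmland habitat classes
#'
#' Canonical class names used throughout the package, in a fixed order:
#' six open-field classes mapped in the field (cereals, root vegetables,
#' pastures, intensive meadows, extensive meadows, wildflower strips) and
#' four structural classes (forests, forest edges, roads, settlements).
#' Wildflower strips and extensive meadows are the agri-environment-scheme
#' (AES) classes.
#'
#' @return character vector of length 10.
#' @export
habitat_classes <- function() {
  c("cereals", "root_vegetables", "pastures", "intensive_meadows",
    "extensive_meadows", "wildflower_strips", "forests", "forest_edges",
    "roads", "settlements")
}

#' Default landscape composition
#'
#' Habitat proportions typical of an intensive western-Swiss farmland
#' mosaic (the mean home-range composition scale: roughly a quarter
#' cereals, a fifth forest, with AES classes rare).
#'
#' @return named numeric vector over [habitat_classes()] summing to 1.
#' @export
default_proportions <- function() {
  p <- c(cereals = 0.246, root_vegetables = 0.104, pastures = 0.071,
         intensive_meadows = 0.115, extensive_meadows = 0.041,
         wildflower_strips = 0.005, forests = 0.181, forest_edges = 0.050,
         roads = 0.084, settlements = 0.103)
  p / sum(p)
}

#' Generate a categorical farmland landscape
#'
#' Builds a planar habitat mosaic by seeded-cell tessellation: Poisson
#' seed points define nearest-seed (Voronoi) cells of characteristic size
#' `patch_scale`, and cells are assigned classes so that realized area
#' fractions track the requested proportions.  Classes rarer than
#' `strip_threshold` (by default only wildflower strips under the default
#' composition) are not given whole cells but are overlaid as thin
#' rectangular strips of width `strip_width`, emulating sown AES strips.
#'
#' A class-lookup raster at resolution `res` is precomputed so that point
#' queries and area summaries are cheap; [habitat_at()] can also answer
#' queries exactly from the seeds and strips.
#'
#' @param proportions named vector of target area fractions over (a subset
#'   of) [habitat_classes()]; must be non-negative and sum to 1.
#' @param patch_scale characteristic patch diameter in metres (mean
#'   Voronoi cell area is `patch_scale^2`).
#' @param region numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param seed integer seed for reproducible generation.
#' @param res lookup-raster resolution in metres.
#' @param strip_threshold classes with target fraction strictly below this
#'   are realized as strips.
#' @param strip_width strip width in metres.
#' @return an object of class `habitat_map`.
#' @examples
#' m <- generate_landscape(default_proportions(), patch_scale = 300,
#'                         region = c(0, 0, 2000, 2000), seed = 1)
#' class_fractions(m)["cereals"]
#' @export
generate_landscape <- function(proportions = default_proportions(),
                               patch_scale = 150,
                               region = c(0, 0, 4000, 4000),
                               seed = NULL, res = 5,
                               strip_threshold = 0.02, strip_width = 10) {
  classes <- habitat_classes()
  if (is.null(names(proportions)) || !all(names(proportions) %in% classes))
    stop("proportions must be named with habitat classes")
  p <- stats::setNames(numeric(length(classes)), classes)
  p[names(proportions)] <- proportions
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  stopifnot(patch_scale > 0, length(region) == 4)
  w <- region[3] - region[1]; h <- region[4] - region[2]
  if (w <= 0 || h <= 0) stop("degenerate region")
  area <- w * h

  strip_cls <- classes[p > 0 & p < strip_threshold]
  cell_cls <- classes[p > 0 & !(classes %in% strip_cls)]
  n_seeds <- max(length(cell_cls), round(area / patch_scale^2))
  if (n_seeds < length(cell_cls))
    stop("region too small to place all classes with nonzero fraction")

  with_seed(seed, {
    seeds <- cbind(x = runif(n_seeds, region[1], region[3]),
                   y = runif(n_seeds, region[2], region[4]))

    ## lookup raster: nearest-seed cell id per grid cell centre
    nx <- max(2L, ceiling(w / res)); ny <- max(2L, ceiling(h / res))
    gx <- region[1] + (seq_len(nx) - 0.5) * (w / nx)
    gy <- region[2] + (seq_len(ny) - 0.5) * (h / ny)
    grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
    cell_id <- nearest_seed(seeds, grid[, 1], grid[, 2])
    cell_area <- res_area <- (w / nx) * (h / ny)
    seed_area <- tabulate(cell_id, nbins = n_seeds) * cell_area

    ## greedy quota assignment of classes to cells (largest remaining
    ## deficit first); strip classes take their share later, uniformly,
    ## so cell quotas are inflated by 1/(1 - strip fraction)
    strip_frac <- sum(p[strip_cls])
    quota <- p[cell_cls] / (1 - strip_frac) * area
    seed_class <- integer(n_seeds)
    for (i in sample.int(n_seeds)) {
      k <- which.max(quota)
      seed_class[i] <- match(cell_cls[k], classes)
      quota[k] <- quota[k] - seed_area[i]
    }

    ## strips: random thin rectangles, total nominal area = target
    strips <- NULL
    for (cl in strip_cls) {
      target <- p[cl] * area
      total_len <- target / strip_width
      lens <- numeric(0)
      while (sum(lens) < total_len)
        lens <- c(lens, runif(1, patch_scale, 2 * patch_scale))
      lens[length(lens)] <- lens[length(lens)] - (sum(lens) - total_len)
      ns <- length(lens)
      ## centre inset so strips fit inside the region at any angle
      mx <- pmin(lens / 2 + strip_width, w / 2 * 0.9)
      my <- pmin(lens / 2 + strip_width, h / 2 * 0.9)
      strips <- rbind(strips, data.frame(
        cx = runif(ns, region[1] + mx, region[3] - mx),
        cy = runif(ns, region[2] + my, region[4] - my),
        len = lens, width = strip_width,
        angle = runif(ns, 0, pi),
        class = match(cl, classes)))
    }

    rast <- seed_class[cell_id]
    if (!is.null(strips) && nrow(strips) > 0) {
      hit <- points_in_strips(grid[, 1], grid[, 2], strips)
      rast[hit > 0] <- strips$class[hit[hit > 0]]
    }

    map <- structure(list(
      region = as.numeric(region), classes = classes,
      proportions = p, patch_scale = patch_scale,
      seeds = seeds, seed_class = seed_class, strips = strips,
      res = res, nx = nx, ny = ny, raster = rast), class = "habitat_map")

    ## verify every requested class is realized somewhere
    got <- classes[sort(unique(rast))]
    missing <- setdiff(classes[p > 0], got)
    if (length(missing) > 0)
      stop("region too small to place all classes with nonzero fraction: ",
           paste(missing, collapse = ", "))
    map
  })
}

## Deterministic nearest-seed index (ties -> lowest seed index); the
## k-nearest-neighbour helpers in recommended packages break near-ties
## at random, which would make map rebuilds non-reproducible.
nearest_seed <- function(seeds, px, py) {
  n <- length(px)
  best <- rep(1L, n)
  bestd <- (px - seeds[1, 1])^2 + (py - seeds[1, 2])^2
  for (i in seq_len(nrow(seeds))[-1]) {
    d <- (px - seeds[i, 1])^2 + (py - seeds[i, 2])^2
    upd <- d < bestd
    if (any(upd)) {
      best[upd] <- i
      bestd[upd] <- d[upd]
    }
  }
  best
}

## For each point, index of the last strip containing it (0 = none).
points_in_strips <- function(x, y, strips) {
  hit <- integer(length(x))
  if (is.null(strips)) return(hit)
  for (i in seq_len(nrow(strips))) {
    dx <- x - strips$cx[i]; dy <- y - strips$cy[i]
    ca <- cos(strips$angle[i]); sa <- sin(strips$angle[i])
    u <- dx * ca + dy * sa      # along strip
    v <- -dx * sa + dy * ca     # across strip
    inside <- abs(u) <= strips$len[i] / 2 & abs(v) <= strips$width[i] / 2
    hit[inside] <- i
  }
  hit
}

#' @export
print.habitat_map <- function(x, ...) {
  w <- x$region[3] - x$region[1]; h <- x$region[4] - x$region[2]
  cat(sprintf("<habitat_map> %.1f x %.1f km, %d seed cells, res %.1f m\n",
              w / 1000, h / 1000, nrow(x$seeds), x$res))
  print(round(class_fractions(x), 3))
  invisible(x)
}

#' Query habitat class at point coordinates
#'
#' @param map a `habitat_map`.
#' @param x,y coordinate vectors in metres.
#' @param method `"raster"` (default; lookup at `map$res` resolution) or
#'   `"exact"` (direct nearest-seed computation with strip override).
#' @return factor over [habitat_classes()], `NA` outside the region.
#' @export
habitat_at <- function(map, x, y, method = c("raster", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "habitat_map"), length(x) == length(y))
  r <- map$region
  inside <- x >= r[1] & x <= r[3] & y >= r[2] & y <= r[4] &
    is.finite(x) & is.finite(y)
  code <- rep(NA_integer_, length(x))
  if (any(inside)) {
    xi <- x[inside]; yi <- y[inside]
    if (method == "raster") {
      ix <- pmin(map$nx, pmax(1L, 1L + floor((xi - r[1]) / ((r[3] - r[1]) / map$nx))))
      iy <- pmin(map$ny, pmax(1L, 1L + floor((yi - r[2]) / ((r[4] - r[2]) / map$ny))))
      code[inside] <- map$raster[(iy - 1L) * map$nx + ix]
    } else {
      id <- nearest_seed(map$seeds, xi, yi)
      ci <- map$seed_class[id]
      hit <- points_in_strips(xi, yi, map$strips)
      ci[hit > 0] <- map$strips$class[hit[hit > 0]]
      code[inside] <- ci
    }
  }
  factor(map$classes[code], levels = map$classes)
}

#' Realized class area fractions of a landscape
#'
#' Area-weighted class histogram computed from the class-lookup raster.
#'
#' @param map a `habitat_map`.
#' @return named numeric vector over all 10 classes (absent classes get 0).
#' @export
class_fractions <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  n <- tabulate(map$raster, nbins = length(map$classes))
  stats::setNames(n / sum(n), map$classes)
}

#' Habitat composition of a disc
#'
#' Class area fractions inside a disc, computed by regular grid sampling
#' at the map's raster resolution.  Portions of the disc outside the
#' mapped region are dropped and fractions renormalized over the covered
#' part (with a warning when coverage is incomplete).
#'
#' @param map a `habitat_map`.
#' @param cx,cy disc centre (m).
#' @param radius disc radius (m).
#' @param warn warn when part of the disc is unmapped.
#' @return named fractions over all classes, summing to 1; attribute
#'   `coverage` gives the mapped fraction of the disc.
#' @export
disc_composition <- function(map, cx, cy, radius, warn = TRUE) {
  stopifnot(inherits(map, "habitat_map"), radius > 0)
  step <- min(map$res, radius / 4)
  s <- seq(-radius + step / 2, radius - step / 2, by = step)
  px <- cx + rep(s, times = length(s))
  py <- cy + rep(s, each = length(s))
  keep <- (px - cx)^2 + (py - cy)^2 <= radius^2
  cl <- habitat_at(map, px[keep], py[keep])
  cov <- mean(!is.na(cl))
  if (cov == 0) stop("disc entirely outside mapped region")
  if (cov < 1 - 1e-9 && warn)
    warning(sprintf("disc extends beyond mapped region (%.0f%% covered); renormalizing",
                    100 * cov))
  tab <- table(cl)
  out <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  attr(out, "coverage") <- cov
  out
}

#' Draw random points lying in a given habitat class
#'
#' Samples raster cells of the class uniformly and jitters within cells;
#' used e.g. to place nest sites inside settlement patches.
#'
#' @param map a `habitat_map`.
#' @param class a habitat class name present on the map.
#' @param n number of points.
#' @return n x 2 matrix of coordinates.
#' @export
sample_points_in_class <- function(map, class, n = 1) {
  stopifnot(inherits(map, "habitat_map"))
  code <- match(class, map$classes)
  if (is.na(code)) stop("unknown class: ", class)
  cells <- which(map$raster == code)
  if (length(cells) == 0) stop("no ", class, " patch available")
  pick <- cells[sample.int(length(cells), n, replace = TRUE)]
  ix <- (pick - 1L) %% map$nx; iy <- (pick - 1L) %/% map$nx
  r <- map$region
  dx <- (r[3] - r[1]) / map$nx; dy <- (r[4] - r[2]) / map$ny
  cbind(x = r[1] + (ix + runif(n)) * dx, y = r[2] + (iy + runif(n)) * dy)
}
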