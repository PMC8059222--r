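## GeoJSON export/import of habitat maps (polygon features with a
## "habitat_class" property) and home-range isopleths.

## Voronoi cell polygon of seed i: the region rectangle clipped by the
## bisector half-plane against every nearby seed (Sutherland-Hodgman).
clip_halfplane <- function(px, py, a, b, c) {
  ## keep {p : a*x + b*y <= c}
  n <- length(px)
  if (n == 0) return(list(x = px, y = py))
  keep <- a * px + b * py <= c
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) { ox <- c(ox, px[i]); oy <- c(oy, py[i]) }
    if (keep[i] != keep[j]) {
      t <- (c - a * px[i] - b * py[i]) /
        (a * (px[j] - px[i]) + b * (py[j] - py[i]))
      ox <- c(ox, px[i] + t * (px[j] - px[i]))
      oy <- c(oy, py[i] + t * (py[j] - py[i]))
    }
  }
  list(x = ox, y = oy)
}

voronoi_cell <- function(map, i) {
  r <- map$region
  poly <- list(x = r[c(1, 3, 3, 1)], y = r[c(2, 2, 4, 4)])
  s <- map$seeds
  d2 <- (s[, 1] - s[i, 1])^2 + (s[, 2] - s[i, 2])^2
  near <- setdiff(which(d2 < (6 * map$patch_scale)^2), i)
  for (j in near) {
    a <- s[j, 1] - s[i, 1]; b <- s[j, 2] - s[i, 2]
    m <- (s[j, ] + s[i, ]) / 2
    poly <- clip_halfplane(poly$x, poly$y, a, b, a * m[1] + b * m[2])
    if (length(poly$x) == 0) break
  }
  poly
}

strip_corners <- function(st) {
  ca <- cos(st$angle); sa <- sin(st$angle)
  u <- c(ca, sa) * st$len / 2; v <- c(-sa, ca) * st$width / 2
  ctr <- c(st$cx, st$cy)
  rbind(ctr + u + v, ctr - u + v, ctr - u - v, ctr + u - v)
}

#' Write a habitat map as GeoJSON
#'
#' One polygon feature per tessellation cell and per strip (strips come
#' last and override the cells they cross), each with a `habitat_class`
#' property.  Generator metadata (seeds, classes, strips, resolution) is
#' stored in a top-level `properties` member so that [read_habitat_geojson()]
#' reconstructs the map exactly.
#'
#' @param map a `habitat_map`.
#' @param path output path.
#' @export
write_habitat_geojson <- function(map, path) {
  feats <- list()
  for (i in seq_len(nrow(map$seeds))) {
    poly <- voronoi_cell(map, i)
    if (length(poly$x) < 3) next
    ring <- lapply(c(seq_along(poly$x), 1), function(k)
      c(poly$x[k], poly$y[k]))
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(habitat_class = map$classes[map$seed_class[i]]),
      geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  if (!is.null(map$strips)) for (i in seq_len(nrow(map$strips))) {
    cc <- strip_corners(map$strips[i, ])
    ring <- lapply(c(1:4, 1), function(k) c(cc[k, 1], cc[k, 2]))
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(habitat_class = map$classes[map$strips$class[i]],
                        strip = TRUE),
      geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  gj <- list(
    type = "FeatureCollection",
    properties = list(
      generator = "owlmove", region = map$region, res = map$res,
      patch_scale = map$patch_scale, classes = map$classes,
      seed_x = map$seeds[, 1], seed_y = map$seeds[, 2],
      seed_class = map$seed_class,
      strips = if (!is.null(map$strips)) map$strips),
    features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read a habitat map from GeoJSON
#'
#' Reconstructs a `habitat_map` from a file written by
#' [write_habitat_geojson()] using the embedded generator metadata (the
#' class-lookup raster is rebuilt, giving an exact round trip).
#'
#' @param path GeoJSON path.
#' @return a `habitat_map`.
#' @export
read_habitat_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pr <- gj$properties
  if (is.null(pr$generator) || pr$generator != "owlmove")
    stop("not an owlmove habitat GeoJSON (missing generator metadata)")
  region <- as.numeric(pr$region)
  seeds <- cbind(x = pr$seed_x, y = pr$seed_y)
  seed_class <- as.integer(pr$seed_class)
  strips <- if (!is.null(pr$strips) && length(pr$strips) > 0)
    as.data.frame(pr$strips)
  res <- pr$res
  w <- region[3] - region[1]; h <- region[4] - region[2]
  nx <- max(2L, ceiling(w / res)); ny <- max(2L, ceiling(h / res))
  gx <- region[1] + (seq_len(nx) - 0.5) * (w / nx)
  gy <- region[2] + (seq_len(ny) - 0.5) * (h / ny)
  grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  cell_id <- nearest_seed(seeds, grid[, 1], grid[, 2])
  rast <- seed_class[cell_id]
  if (!is.null(strips)) {
    hit <- points_in_strips(grid[, 1], grid[, 2], strips)
    rast[hit > 0] <- strips$class[hit[hit > 0]]
  }
  structure(list(region = region, classes = as.character(pr$classes),
                 proportions = NULL, patch_scale = pr$patch_scale,
                 seeds = seeds, seed_class = seed_class, strips = strips,
                 res = res, nx = nx, ny = ny, raster = rast),
            class = "habitat_map")
}

#' Write home-range isopleth polygons as GeoJSON
#'
#' Contour polygons of the kernel density surface at the isopleth level,
#' with the area and level as feature properties.
#'
#' @param hr a `home_range`.
#' @param path output path.
#' @param individual_id optional id recorded on the features.
#' @export
write_home_range_geojson <- function(hr, path, individual_id = NA) {
  cl <- grDevices::contourLines(hr$gx, hr$gy, hr$dens, levels = hr$level)
  feats <- lapply(cl, function(cc) {
    ring <- lapply(c(seq_along(cc$x), 1), function(k) c(cc$x[k], cc$y[k]))
    list(type = "Feature",
         properties = list(individual_id = individual_id, q = hr$q,
                           area_km2 = hr$area_km2),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}
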