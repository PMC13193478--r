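#' Validate longitude/latitude points
#'
#' @param points Two-column matrix or data.frame (lon, lat in degrees).
#' @return A numeric matrix with columns `lon`, `lat`.
#' @export
validate_points <- function(points) {
  p <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(p) <- "double"
  colnames(p) <- c("lon", "lat")
  if (any(!is.finite(p))) stop("non-finite coordinates")
  if (any(p[, 1] < -180 | p[, 1] > 180)) stop("longitude outside [-180, 180]")
  if (any(p[, 2] < -90 | p[, 2] > 90)) stop("latitude outside [-90, 90]")
  p
}

#' Point-in-polygon test (winding number)
#'
#' @param points Matrix of (lon, lat) points.
#' @param polygon Matrix of polygon vertices (closed or open ring).
#' @return Logical vector; points exactly on an edge count as inside.
#' @export
point_in_polygon <- function(points, polygon) {
  p <- as.matrix(points)
  poly <- close_ring(as.matrix(polygon))
  n <- nrow(poly) - 1
  vapply(seq_len(nrow(p)), function(i) {
    x <- p[i, 1]; y <- p[i, 2]
    wn <- 0
    for (j in seq_len(n)) {
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[j + 1, 1]; y2 <- poly[j + 1, 2]
      # boundary counts as inside
      cr <- (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1)
      if (cr == 0 && min(x1, x2) <= x && x <= max(x1, x2) &&
          min(y1, y2) <= y && y <= max(y1, y2)) return(TRUE)
      if (y1 <= y) {
        if (y2 > y && cr > 0) wn <- wn + 1
      } else {
        if (y2 <= y && cr < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

close_ring <- function(poly) {
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Convex hull of occurrence points
#'
#' Minimal convex polygon containing the points.  Degenerate inputs (fewer
#' than 3 distinct points, or collinear points) are buffered by `buffer` on
#' each side, giving a small rectangle, so every species gets a usable range
#' polygon.
#'
#' @param points Matrix of (lon, lat).
#' @param buffer Degrees used to buffer degenerate hulls (one grid cell of
#'   the default 30 arc-second environmental grid by default).
#' @return Matrix of hull vertices (open ring, counterclockwise).
#' @export
convex_hull <- function(points, buffer = 1 / 120) {
  p <- unique(validate_points(points))
  if (nrow(p) < 1) stop("at least one point required")
  idx <- chull(p)
  if (nrow(p) >= 3 && length(idx) >= 3) return(p[rev(idx), , drop = FALSE])
  # degenerate: buffered bounding box of the point/segment
  rx <- range(p[, 1]); ry <- range(p[, 2])
  cbind(lon = c(rx[1] - buffer, rx[2] + buffer, rx[2] + buffer,
                rx[1] - buffer),
        lat = c(ry[1] - buffer, ry[1] - buffer, ry[2] + buffer,
                ry[2] + buffer))
}

#' Planar polygon area (shoelace formula, squared degrees)
#' @param polygon Vertex matrix.
#' @export
polygon_area <- function(polygon) {
  poly <- close_ring(as.matrix(polygon))
  n <- nrow(poly) - 1
  abs(sum(poly[1:n, 1] * poly[2:(n + 1), 2] -
            poly[2:(n + 1), 1] * poly[1:n, 2])) / 2
}

#' Random grid-cell centers inside a polygon
#'
#' Samples `n` distinct cell centers of a regular lon/lat grid that fall
#' inside the polygon, uniformly without replacement; "without replacement"
#' is defined over the cells of the environmental grid.
#'
#' @param polygon Vertex matrix.
#' @param n Number of points (the analysis default is 20).
#' @param grid_res Grid resolution in degrees (default 30 arc seconds).
#' @param seed Integer seed.
#' @param origin Grid origin (lon, lat) the cells are aligned to.
#' @return Matrix of points; fewer than `n` (with a warning) when the
#'   polygon intersects fewer cells.
#' @export
random_points_in_polygon <- function(polygon, n = 20, grid_res = 1 / 120,
                                     seed = 1, origin = c(-180, -90)) {
  poly <- as.matrix(polygon)
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  ix <- floor((rx - origin[1]) / grid_res); iy <- floor((ry - origin[2]) /
                                                          grid_res)
  cx <- origin[1] + (seq(ix[1], ix[2]) + 0.5) * grid_res
  cy <- origin[2] + (seq(iy[1], iy[2]) + 0.5) * grid_res
  centers <- cbind(lon = rep(cx, times = length(cy)),
                   lat = rep(cy, each = length(cx)))
  inside <- centers[point_in_polygon(centers, poly), , drop = FALSE]
  if (nrow(inside) == 0) stop("no grid cells inside polygon")
  set.seed(seed)
  if (nrow(inside) <= n) {
    if (nrow(inside) < n)
      warning("only ", nrow(inside), " grid cells inside polygon",
              call. = FALSE)
    return(inside[sample.int(nrow(inside)), , drop = FALSE])
  }
  inside[sample.int(nrow(inside), n), , drop = FALSE]
}

#' Great-circle distance matrix (haversine, km)
#' @param points Matrix of (lon, lat) degrees.
#' @export
haversine_km <- function(points) {
  p <- validate_points(points)
  n <- nrow(p)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d[i, (i + 1):n] <- geosphere::distHaversine(
        p[i, , drop = FALSE], p[(i + 1):n, , drop = FALSE],
        r = 6371008.8) / 1000
    }
    d <- d + t(d)
  }
  d
}

#' Spatially thin points to a minimum pairwise distance
#'
#' Greedy max-conflict removal: iteratively drops the point with the most
#' neighbors closer than `min_km` (haversine), breaking ties at random under
#' `seed`, until no pair violates the constraint.  Idempotent on its own
#' output.
#'
#' @param points Matrix of (lon, lat).
#' @param min_km Minimum distance (km), default 1.5.
#' @param seed Integer seed for tie-breaks.
#' @return The retained points (original row order preserved).
#' @export
thin_points <- function(points, min_km = 1.5, seed = 1) {
  stopifnot(min_km > 0)
  p <- validate_points(points)
  if (nrow(p) <= 1) return(p)
  d <- haversine_km(p)
  conflict <- d < min_km
  diag(conflict) <- FALSE
  keep <- rep(TRUE, nrow(p))
  set.seed(seed)
  repeat {
    cnt <- rowSums(conflict[keep, keep, drop = FALSE])
    if (all(cnt == 0)) break
    worst <- which(cnt == max(cnt))
    drop_local <- if (length(worst) > 1) sample(worst, 1) else worst
    keep[which(keep)[drop_local]] <- FALSE
  }
  p[keep, , drop = FALSE]
}

#' Keep only occurrences inside a species' native-range polygons
#'
#' @param occ data.frame with columns `species`, `lon`, `lat`.
#' @param polygons Named list (by species) of polygon vertex matrices, or of
#'   lists of such matrices (multi-part ranges).
#' @param missing_species What to do with species absent from the polygon
#'   table: `"warn"` (retain all their points, flagged) or `"drop"`.
#' @return The filtered data.frame; attribute `removed` counts dropped
#'   points per species.
#' @export
filter_native <- function(occ, polygons,
                          missing_species = c("warn", "drop")) {
  missing_species <- match.arg(missing_species)
  validate_points(occ[, c("lon", "lat")])
  if (anyDuplicated(occ[, c("species", "lon", "lat")]))
    occ <- occ[!duplicated(occ[, c("species", "lon", "lat")]), ]
  keep <- logical(nrow(occ))
  for (sp in unique(occ$species)) {
    rows <- which(occ$species == sp)
    polys <- polygons[[sp]]
    if (is.null(polys)) {
      if (missing_species == "warn") {
        warning("no native polygon for ", sp, "; points retained",
                call. = FALSE)
        keep[rows] <- TRUE
      }
      next
    }
    if (is.matrix(polys) || is.data.frame(polys)) polys <- list(polys)
    inside <- Reduce(`|`, lapply(polys, function(pg)
      point_in_polygon(occ[rows, c("lon", "lat")], pg)))
    keep[rows] <- inside
  }
  out <- occ[keep, , drop = FALSE]
  removed <- table(occ$species[!keep])
  attr(out, "removed") <- removed
  out
}

#' Read species range polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features with a
#' `species` property; only the WGS84 outer rings are used.
#'
#' @param path GeoJSON file.
#' @return Named list of lists of vertex matrices.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    sp <- f$properties$species
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1),
      stop("unsupported geometry type: ", geom$type))
    out[[sp]] <- lapply(rings, function(r)
      do.call(rbind, lapply(r, function(xy)
        c(lon = xy[[1]], lat = xy[[2]]))))
  }
  out
}

#' Write species range polygons to GeoJSON
#' @param polygons Named list as in [read_polygons_geojson()].
#' @param path Output file.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(names(polygons), function(sp) {
    polys <- polygons[[sp]]
    if (is.matrix(polys) || is.data.frame(polys)) polys <- list(polys)
    coords <- lapply(polys, function(pg) {
      pg <- close_ring(as.matrix(pg))
      list(lapply(seq_len(nrow(pg)), function(i) c(pg[i, 1], pg[i, 2])))
    })
    list(type = "Feature", properties = list(species = sp),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
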