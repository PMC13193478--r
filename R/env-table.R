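#' In-memory environmental grid
#'
#' A regular lon/lat grid holding one matrix per environmental layer; the
#' value of cell (i, j) sits at center `(xmin + (i - 0.5) res,
#' ymin + (j - 0.5) res)`.  This is the lookup used for extraction; gridded
#' CSV is the on-disk form.
#'
#' @param xmin,ymin Lower-left corner (degrees).
#' @param res Cell size (degrees).
#' @param layers Named list of numeric matrices (nx rows, ny columns), all
#'   the same dimension.
#' @export
env_grid <- function(xmin, ymin, res, layers) {
  stopifnot(res > 0, length(layers) >= 1, !is.null(names(layers)))
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) stop("all layers must share one dimension")
  structure(list(xmin = xmin, ymin = ymin, res = res,
                 nx = dims[[1]][1], ny = dims[[1]][2], layers = layers),
            class = "env_grid")
}

#' Extract environmental values at points (nearest cell)
#'
#' @param grid An [env_grid()].
#' @param points Matrix of (lon, lat).
#' @param layers Layer names (default all).
#' @return data.frame, one row per point; `NA` outside the grid.
#' @export
env_extract <- function(grid, points, layers = names(grid$layers)) {
  p <- validate_points(points)
  i <- floor((p[, 1] - grid$xmin) / grid$res) + 1L
  j <- floor((p[, 2] - grid$ymin) / grid$res) + 1L
  ok <- i >= 1 & i <= grid$nx & j >= 1 & j <= grid$ny
  out <- lapply(layers, function(l) {
    v <- rep(NA_real_, nrow(p))
    v[ok] <- grid$layers[[l]][cbind(i[ok], j[ok])]
    v
  })
  names(out) <- layers
  as.data.frame(out)
}

#' Write / read an environmental grid as plain CSV
#'
#' Long format with columns `lon`, `lat` (cell centers) and one column per
#' layer; the affine header (origin and resolution) is reconstructed from
#' the coordinates on read.
#'
#' @param grid An [env_grid()].
#' @param path CSV path.
#' @export
write_env_grid <- function(grid, path) {
  cx <- grid$xmin + (seq_len(grid$nx) - 0.5) * grid$res
  cy <- grid$ymin + (seq_len(grid$ny) - 0.5) * grid$res
  df <- data.frame(lon = rep(cx, times = grid$ny),
                   lat = rep(cy, each = grid$nx))
  for (l in names(grid$layers)) df[[l]] <- as.vector(grid$layers[[l]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  df <- read.csv(path)
  cx <- sort(unique(df$lon)); cy <- sort(unique(df$lat))
  res <- min(diff(cx))
  nx <- length(cx); ny <- length(cy)
  layers <- lapply(setdiff(names(df), c("lon", "lat")), function(l) {
    m <- matrix(NA_real_, nx, ny)
    i <- round((df$lon - cx[1]) / res) + 1L
    j <- round((df$lat - cy[1]) / res) + 1L
    m[cbind(i, j)] <- df[[l]]
    m
  })
  names(layers) <- setdiff(names(df), c("lon", "lat"))
  env_grid(cx[1] - res / 2, cy[1] - res / 2, res, layers)
}

#' Species-level environmental summary table
#'
#' For every species: if it has at least `min_records` cleaned occurrence
#' points, those points are spatially thinned and used; otherwise
#' `n_random` random grid-cell points are drawn inside its range polygon
#' (supplied, or the convex hull of what points it has) and thinned.  A
#' species never mixes observed and random points.  Per-species value = mean
#' (or median) of the layer over its points.
#'
#' @param occ data.frame with `species`, `lon`, `lat` (already
#'   native-filtered).
#' @param grid An [env_grid()] with the environmental layers.
#' @param polygons Optional named list of range polygons for the
#'   random-point path.
#' @param min_records Observed-point threshold (default 5).
#' @param n_random Random points for data-poor species (default 20).
#' @param thin_km Thinning distance in km (default 1.5).
#' @param seed Integer seed.
#' @param aggregate_fun `"mean"` (default) or `"median"`.
#' @return data.frame with species, per-layer values, `n_points`,
#'   `provenance` (`"observed"`/`"random"`); attribute `excluded` lists
#'   species with neither enough points nor a polygon.
#' @export
species_env_summary <- function(occ, grid, polygons = NULL, min_records = 5,
                                n_random = 20, thin_km = 1.5, seed = 1,
                                aggregate_fun = c("mean", "median")) {
  aggregate_fun <- match.arg(aggregate_fun)
  agg <- if (aggregate_fun == "mean") mean else median
  species <- sort(unique(c(occ$species, names(polygons))))
  rows <- list()
  excluded <- character(0)
  for (si in seq_along(species)) {
    sp <- species[si]
    pts <- as.matrix(occ[occ$species == sp, c("lon", "lat"), drop = FALSE])
    sp_seed <- seed + si
    if (nrow(pts) >= min_records) {
      use <- thin_points(pts, min_km = thin_km, seed = sp_seed)
      prov <- "observed"
    } else {
      poly <- polygons[[sp]]
      if (is.null(poly) && nrow(pts) >= 1)
        poly <- convex_hull(pts, buffer = grid$res)
      if (is.null(poly)) { excluded <- c(excluded, sp); next }
      if (is.list(poly) && !is.matrix(poly)) poly <- poly[[1]]
      rp <- random_points_in_polygon(poly, n = n_random, grid_res = grid$res,
                                     seed = sp_seed,
                                     origin = c(grid$xmin, grid$ymin))
      use <- thin_points(rp, min_km = thin_km, seed = sp_seed)
      prov <- "random"
    }
    vals <- env_extract(grid, use)
    vals <- vals[complete.cases(vals), , drop = FALSE]
    if (nrow(vals) == 0) { excluded <- c(excluded, sp); next }
    rows[[sp]] <- data.frame(species = sp, t(apply(vals, 2, agg)),
                             n_points = nrow(vals), provenance = prov)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing each column on the others.
#' Perfect collinearity is reported as `Inf` together with the offending
#' regression.
#'
#' @param x data.frame or matrix of numeric predictor columns.
#' @param threshold Flagging threshold (default 5).
#' @return data.frame with `variable`, `vif`, `flagged`.
#' @export
vif <- function(x, threshold = 5) {
  x <- as.data.frame(x)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(x) < 2) stop("need at least 2 numeric columns")
  if (nrow(x) <= ncol(x)) stop("need more rows than columns")
  out <- data.frame(variable = names(x), vif = NA_real_)
  for (j in seq_along(x)) {
    fit <- lm(x[[j]] ~ ., data = x[-j])
    r2 <- 1 - sum(resid(fit)^2) / sum((x[[j]] - mean(x[[j]]))^2)
    if (r2 >= 1 - 1e-12) {
      out$vif[j] <- Inf
      warning("perfect collinearity: ", names(x)[j], " ~ ",
              paste(names(x)[-j], collapse = " + "), call. = FALSE)
    } else out$vif[j] <- 1 / (1 - r2)
  }
  out$flagged <- out$vif > threshold
  out
}

#' Center and scale columns by two standard deviations
#'
#' `x' = (x - mean) / (2 sd)`, the convention that puts continuous and
#' binary predictors on comparable scales; scaling constants are stored for
#' back-transformation with [unscale_2sd()].
#'
#' @param x data.frame or matrix of numeric columns.
#' @return Scaled data.frame with attributes `center` and `scale`.
#' @export
scale_2sd <- function(x) {
  x <- as.data.frame(x)
  ctr <- vapply(x, mean, numeric(1))
  s <- vapply(x, sd, numeric(1))
  if (any(s == 0))
    stop("zero-variance column(s): ",
         paste(names(x)[s == 0], collapse = ", "))
  out <- as.data.frame(mapply(function(col, m, sc) (col - m) / (2 * sc),
                              x, ctr, s, SIMPLIFY = FALSE))
  attr(out, "center") <- ctr
  attr(out, "scale") <- 2 * s
  out
}

#' @rdname scale_2sd
#' @param scaled A data.frame produced by [scale_2sd()].
#' @export
unscale_2sd <- function(scaled) {
  ctr <- attr(scaled, "center"); sc <- attr(scaled, "scale")
  as.data.frame(mapply(function(col, m, s) col * s + m, scaled, ctr, sc,
                       SIMPLIFY = FALSE))
}
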