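test_that("coordinate validation enforces lon/lat ranges", {
  expect_error(validate_points(cbind(200, 0)), "longitude")
  expect_error(validate_points(cbind(0, -95)), "latitude")
  p <- validate_points(data.frame(a = 1:2, b = 3:4))
  expect_equal(colnames(p), c("lon", "lat"))
})

test_that("point-in-polygon agrees with an even-odd ray-casting oracle", {
  set.seed(71)
  agree <- 0
  total <- 0
  for (rep in 1:20) {
    k <- sample(3:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    poly <- cbind(cos(ang) * runif(k, .5, 2), sin(ang) * runif(k, .5, 2))
    pts <- cbind(runif(50, -2.5, 2.5), runif(50, -2.5, 2.5))
    total <- total + 50
    agree <- agree + sum(point_in_polygon(pts, poly) ==
                           raycast_in_polygon(pts, poly))
  }
  expect_equal(agree, total)  # 1000 random cases
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_true(point_in_polygon(cbind(.5, .5), sq))
  expect_false(point_in_polygon(cbind(1.5, .5), sq))
})

test_that("convex hulls contain their points and match a brute-force area", {
  sq <- cbind(lon = c(0, 1, 1, 0, .5), lat = c(0, 0, 1, 1, .5))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4)
  expect_equal(polygon_area(h), 1)
  set.seed(72)
  for (rep in 1:5) {
    pts <- cbind(lon = runif(10, -3, 3), lat = runif(10, -3, 3))
    h <- convex_hull(pts)
    expect_true(all(point_in_polygon(pts, h)))
    expect_true(all(apply(h, 1, function(v)
      any(abs(pts[, 1] - v[1]) + abs(pts[, 2] - v[2]) < 1e-12))))
    expect_equal(polygon_area(h), hull_area_bruteforce(pts),
                 tolerance = 1e-10)
  }
  seg <- cbind(lon = c(0, 1), lat = c(0, 0))
  hd <- convex_hull(seg, buffer = 0.1)
  expect_equal(nrow(hd), 4)
  expect_gt(polygon_area(hd), 0)
  expect_error(convex_hull(matrix(numeric(0), 0, 2)))
})

test_that("random in-polygon points are grid centers, seeded, near-uniform", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  # exactly 20 cells in a 5 x 4 cover
  expect_warning(
    p <- random_points_in_polygon(sq + 0.001, n = 20, grid_res = 0.25,
                                  seed = 1, origin = c(0, 0)),
    "16 grid cells")
  expect_equal(nrow(p), 16)  # 4 x 4 centers strictly inside
  a <- random_points_in_polygon(sq, n = 5, grid_res = 0.1, seed = 3,
                                origin = c(0, 0))
  b <- random_points_in_polygon(sq, n = 5, grid_res = 0.1, seed = 3,
                                origin = c(0, 0))
  d <- random_points_in_polygon(sq, n = 5, grid_res = 0.1, seed = 4,
                                origin = c(0, 0))
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_equal(nrow(unique(a)), 5)
  # frequency test over a 100-cell polygon
  counts <- table(unlist(lapply(1:2000, function(s) {
    q <- random_points_in_polygon(sq, n = 5, grid_res = 0.1, seed = s,
                                  origin = c(0, 0))
    paste(round(q[, 1], 3), round(q[, 2], 3))
  })))
  expect_equal(length(counts), 100)
  expf <- 2000 * 5 / 100
  sdv <- sqrt(2000 * 5 * (1 / 100) * (99 / 100))
  expect_true(all(abs(counts - expf) < 3.9 * sdv))
})

test_that("thinning enforces the minimum distance and is idempotent", {
  # two points 1.0 km apart -> one survives; 2.0 km apart -> both
  p_close <- rbind(c(0, 0), c(0, 1 / 111.195))
  p_far <- rbind(c(0, 0), c(0, 2 / 111.195))
  expect_equal(nrow(thin_points(p_close, 1.5, seed = 1)), 1)
  expect_equal(nrow(thin_points(p_far, 1.5, seed = 1)), 2)
  set.seed(73)
  for (rep in 1:10) {
    pts <- cbind(runif(50, 0, 0.05), runif(50, 0, 0.05))
    th <- thin_points(pts, 1.5, seed = rep)
    d <- haversine_km(th)
    expect_true(all(d[upper.tri(d)] >= 1.5))
    th2 <- thin_points(th, 1.5, seed = rep)
    expect_equal(th, th2)
  }
})

test_that("greedy thinning keeps at least 80% of the exact optimum", {
  set.seed(74)
  for (rep in 1:10) {
    pts <- cbind(runif(12, 0, 0.04), runif(12, 0, 0.04))
    adj <- haversine_km(pts) < 1.5
    diag(adj) <- FALSE
    opt <- mis_size(adj)
    got <- nrow(thin_points(pts, 1.5, seed = rep))
    expect_gte(got, 0.8 * opt)
  }
})

test_that("native filtering keeps in-range points and flags unknown species", {
  occ <- data.frame(species = c("a", "a", "b", "c"),
                    lon = c(.5, 5, .5, .5), lat = c(.5, .5, .5, .5))
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  polys <- list(a = sq, b = sq)
  expect_warning(out <- filter_native(occ, polys), "no native polygon")
  expect_equal(nrow(out), 3)  # a@5,.5 dropped; c retained with warning
  out2 <- suppressWarnings(filter_native(occ, polys,
                                         missing_species = "drop"))
  expect_equal(sort(unique(out2$species)), c("a", "b"))
  expect_error(filter_native(data.frame(species = "a", lon = 200, lat = 0),
                             polys), "longitude")
})

test_that("grid extraction is a nearest-cell lookup with CSV round-trip", {
  layers <- list(v = matrix(1:12, 4, 3))
  g <- env_grid(0, 0, 0.5, layers)
  got <- env_extract(g, rbind(c(0.3, 0.2), c(1.9, 1.4), c(5, 5)))
  expect_equal(got$v, c(1, 12, NA))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_env_grid(g, tf)
  g2 <- read_env_grid(tf)
  expect_equal(g2$layers$v, g$layers$v)
  expect_equal(g2$res, 0.5)
})

test_that("species environmental summaries route sparse species to random points", {
  set.seed(75)
  grid <- env_grid(0, 0, 0.1, list(cst = matrix(7, 60, 60),
                                   grad = outer(1:60, rep(1, 60)) * 1.0))
  sq <- cbind(c(1, 5, 5, 1), c(1, 1, 5, 5))
  occ <- data.frame(
    species = c(rep("rich", 8), rep("poor", 3)),
    lon = c(seq(1.2, 4.8, length.out = 8), 2, 2.5, 3),
    lat = c(seq(1.2, 4.8, length.out = 8), 2, 2.5, 3))
  tab <- species_env_summary(occ, grid, polygons = list(poor = sq),
                             min_records = 5, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$provenance[tab$species == "rich"], "observed")
  expect_equal(tab$provenance[tab$species == "poor"], "random")
  expect_equal(tab$cst, c(7, 7))  # constant layer -> constant value
  # species with neither data nor polygon are excluded and listed
  tab2 <- species_env_summary(occ[occ$species == "rich", ], grid,
                              polygons = list(ghost = NULL), seed = 2)
  expect_equal(tab2$species, "rich")
})

test_that("a linear gradient layer yields the centroid value of the points", {
  nx <- 200
  grid <- env_grid(0, 0, 0.02, list(lin = outer(seq_len(nx) * 1.0,
                                                rep(1, nx))))
  set.seed(76)
  pts <- cbind(runif(30, 0.5, 3.5), runif(30, 0.5, 3.5))
  occ <- data.frame(species = "s", lon = pts[, 1], lat = pts[, 2])
  tab <- species_env_summary(occ, grid, min_records = 5, thin_km = 0.001,
                             seed = 3)
  # layer value = column index = lon / res + 0.5
  expect_equal(tab$lin, mean(pts[, 1]) / 0.02 + 0.5, tolerance = 0.5)
})

test_that("VIF matches its closed forms and detects perfect collinearity", {
  set.seed(77)
  n <- 400
  # orthogonalized pair -> VIF 1
  a <- rnorm(n); b <- resid(lm(rnorm(n) ~ a))
  v0 <- vif(data.frame(a = a, b = b))
  expect_equal(v0$vif, c(1, 1), tolerance = 1e-12)
  # correlation 0.93 -> 1 / (1 - r^2) = 7.37
  x1 <- rnorm(n)
  x2 <- 0.93 * x1 + sqrt(1 - 0.93^2) * rnorm(n)
  r <- cor(x1, x2)
  v <- vif(data.frame(x1, x2))
  expect_equal(v$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  expect_equal(1 / (1 - 0.93^2), 7.4019, tolerance = 1e-4)
  expect_true(all(v$flagged == (v$vif > 5)))
  # three columns against an explicit normal-equations oracle
  x3 <- 0.4 * x1 - 0.2 * x2 + rnorm(n)
  X <- cbind(x1, x2, x3)
  j <- 3
  Z <- cbind(1, X[, -j])
  bh <- solve(crossprod(Z), crossprod(Z, X[, j]))
  r2 <- 1 - sum((X[, j] - Z %*% bh)^2) / sum((X[, j] - mean(X[, j]))^2)
  v3 <- vif(as.data.frame(X))
  expect_equal(v3$vif[3], 1 / (1 - r2), tolerance = 1e-8)
  w <- testthat::capture_warnings(vc <- vif(data.frame(x1, x2,
                                                       s = x1 + x2)))
  expect_match(w, "perfect collinearity", all = FALSE)
  expect_true(any(is.infinite(vc$vif)))
  expect_true(all(v3$vif >= 1))
})

test_that("2-SD scaling yields SD 0.5, mean 0, and round-trips exactly", {
  set.seed(78)
  d <- data.frame(a = rnorm(50, 10, 3), b = runif(50))
  s <- scale_2sd(d)
  expect_equal(unname(vapply(s, sd, numeric(1))), c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(unname(vapply(s, mean, numeric(1))), c(0, 0),
               tolerance = 1e-12)
  back <- unscale_2sd(s)
  expect_equal(back$a, d$a, tolerance = 1e-12)
  expect_error(scale_2sd(data.frame(a = rep(1, 5))), "zero-variance")
})
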