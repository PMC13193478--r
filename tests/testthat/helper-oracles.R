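# Independent oracles and small fixtures used across the suite.  Every
# oracle here is deliberately implemented by a different route than the
# package code it checks.

# coalescent tree rescaled to a given height (ultrametric)
sim_tree <- function(n, height = 10, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * height /
    max(ape::node.depth.edgelength(tr))
  tr
}

# exhaustive-enumeration Mk likelihood: sum over all interior-state
# assignments of prior x product of per-edge transition probabilities,
# with transition probabilities from a scaled matrix exponential (series),
# not from the package's closed form
enum_mk_loglik <- function(tree, states, q01, q10, prior = c(0.5, 0.5)) {
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  mexp <- function(t) {
    A <- Q * t
    S <- diag(2)
    term <- diag(2)
    for (k in 1:60) {
      term <- term %*% A / k
      S <- S + term
    }
    S
  }
  combos <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    node_st <- c(states[tree$tip.label], combos[r, ])
    pr <- prior[node_st[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mexp(tree$edge.length[e])
      pr <- pr * P[node_st[tree$edge[e, 1]] + 1, node_st[tree$edge[e, 2]] + 1]
    }
    tot <- tot + pr
  }
  log(tot)
}

# fixed-step explicit-Euler integration of the SSE D/E equations, with the
# same tip/node conventions as the package (weighted root, crown survival
# conditioning)
euler_sse_loglik <- function(tree, states, spec, par, dt = 1e-4) {
  arr <- leafhabit::sse_expand_params(spec, par)
  slice <- if (spec$sliced) spec$slice_age else -1
  n_tip <- ape::Ntip(tree)
  dep <- ape::node.depth.edgelength(tree)
  h <- max(dep[seq_len(n_tip)])
  age <- pmax(h - dep, 0)
  rates <- function(t) {
    e <- if (t > slice) 1 else 2
    Q <- matrix(arr$qflat[(e - 1) * 16 + 1:16], 4, 4, byrow = TRUE)
    list(lam = arr$lambda[e, ], mu = arr$mu[e, ], Q = Q, qr = rowSums(Q))
  }
  integ <- function(y, t0, t1) {
    t <- t0
    while (t < t1 - 1e-12) {
      hh <- min(dt, t1 - t)
      if (t < slice && t + hh > slice) hh <- slice - t
      r <- rates(t + 1e-12)
      E <- y[1:4]; D <- y[5:8]
      dE <- r$mu - (r$lam + r$mu + r$qr) * E + r$lam * E^2 +
        as.vector(r$Q %*% E)
      dD <- -(r$lam + r$mu + r$qr) * D + 2 * r$lam * E * D +
        as.vector(r$Q %*% D)
      y <- y + hh * c(dE, dD)
      t <- t + hh
    }
    y
  }
  n_node <- n_tip + tree$Nnode
  Y <- matrix(0, n_node, 8)
  rho <- spec$sampling_fraction
  st <- states[tree$tip.label]
  for (i in seq_len(n_tip)) for (s in 1:4) {
    obs <- (s - 1) %% 2
    Y[i, s] <- 1 - rho[obs + 1]
    Y[i, 4 + s] <- if (obs == st[i]) rho[obs + 1] else 0
  }
  pt <- ape::reorder.phylo(tree, "postorder")
  kids <- split(pt$edge[, 2], pt$edge[, 1])
  logsc <- 0
  done <- c(rep(TRUE, n_tip), rep(FALSE, tree$Nnode))
  repeat {
    ready <- as.integer(names(kids))
    ready <- ready[!done[ready] &
                     vapply(kids[as.character(ready)],
                            function(k) all(done[k]), logical(1))]
    if (length(ready) == 0) break
    for (v in ready) {
      r <- rates(age[v] + 1e-12)
      Dacc <- rep(1, 4); Eacc <- rep(0, 4)
      ck <- kids[[as.character(v)]]
      for (c in ck) {
        y <- integ(Y[c, ], age[c], age[v])
        Dacc <- Dacc * y[5:8]; Eacc <- Eacc + y[1:4]
      }
      Y[v, 5:8] <- Dacc * r$lam^(length(ck) - 1)
      Y[v, 1:4] <- Eacc / length(ck)
      s <- sum(Y[v, 5:8])
      Y[v, 5:8] <- Y[v, 5:8] / s
      logsc <- logsc + log(s)
      done[v] <- TRUE
    }
  }
  root <- n_tip + 1
  r <- rates(age[root] + 1e-12)
  w <- Y[root, 5:8] / sum(Y[root, 5:8])
  lik <- sum(w * Y[root, 5:8] / (r$lam * (1 - Y[root, 1:4])^2))
  log(lik) + logsc
}

# forward-simulate an unconditioned binary-regime history along a tree,
# returning the painting and the tip states it implies
sim_regime_history <- function(tree, q01, q10, root_state = 0L, seed = 1) {
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  st <- integer(n_node)
  st[n_tip + 1L] <- root_state
  maps <- vector("list", nrow(tree$edge))
  pt <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(pt$edge)))
  row_of <- match(paste(pt$edge[, 1], pt$edge[, 2]),
                  paste(tree$edge[, 1], tree$edge[, 2]))
  rates <- c(q01, q10)
  for (i in ord) {
    par <- pt$edge[i, 1]; ch <- pt$edge[i, 2]; len <- pt$edge.length[i]
    s <- st[par]; tcur <- 0; bounds <- numeric(0)
    repeat {
      r <- rates[s + 1L]
      if (r <= 0) break
      dt <- rexp(1, r)
      if (tcur + dt >= len) break
      tcur <- tcur + dt
      bounds <- c(bounds, tcur)
      s <- 1L - s
    }
    segs <- diff(c(0, bounds, len))
    sts <- rep(c(st[par], 1L - st[par]), length.out = length(segs))
    maps[[row_of[i]]] <- setNames(segs, as.character(sts))
    st[ch] <- s
  }
  list(map = structure(list(tree = tree, maps = maps, node_states = st),
                       class = "regime_map"),
       states = setNames(st[seq_len(n_tip)], tree$tip.label))
}

# even-odd ray casting (horizontal ray to +infinity); independent of the
# package's winding-number routine
raycast_in_polygon <- function(points, polygon) {
  poly <- as.matrix(polygon)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  apply(as.matrix(points), 1, function(p) {
    x <- p[1]; y <- p[2]
    crossings <- 0
    for (j in seq_len(nrow(poly) - 1)) {
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[j + 1, 1]; y2 <- poly[j + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) crossings <- crossings + 1
      }
    }
    crossings %% 2 == 1
  })
}

# brute-force convex hull area: sum of triangle fan areas over hull built by
# testing every point subset is unnecessary -- instead compute the area as
# the max over all triangles is wrong; use the exact formula by summing
# signed triangle areas from the centroid of the hull vertex candidates:
# here, the area of the convex hull equals the area of the polygon formed by
# ordering all extreme points by angle around the centroid
hull_area_bruteforce <- function(points) {
  p <- unique(as.matrix(points))
  n <- nrow(p)
  # a point is a hull vertex iff it is not strictly inside any triangle of
  # three other points
  in_tri <- function(q, a, b, c) {
    d1 <- (q[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (q[2] - b[2])
    d2 <- (q[1] - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (q[2] - c[2])
    d3 <- (q[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (q[2] - a[2])
    (d1 <= 0 && d2 <= 0 && d3 <= 0) || (d1 >= 0 && d2 >= 0 && d3 >= 0)
  }
  extreme <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    combs <- utils::combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      tri <- combs[, k]
      if (in_tri(p[i, ], p[tri[1], ], p[tri[2], ], p[tri[3], ])) {
        # strictly inside only (not a vertex of the triangle edge)
        if (!any(apply(p[tri, ], 1, function(v) all(v == p[i, ])))) {
          extreme[i] <- FALSE
          break
        }
      }
    }
    if (!extreme[i]) next
  }
  hp <- p[extreme, , drop = FALSE]
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, ]
  m <- nrow(hp)
  abs(sum(hp[, 1] * hp[c(2:m, 1), 2] - hp[c(2:m, 1), 1] * hp[, 2])) / 2
}

# exact maximum independent set size on the conflict graph (points closer
# than min_km are adjacent); exponential search, small n only
mis_size <- function(adj) {
  n <- nrow(adj)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      pairs <- utils::combn(sel, 2)
      for (k in seq_len(ncol(pairs)))
        if (adj[pairs[1, k], pairs[2, k]]) { ok <- FALSE; break }
    }
    if (ok) best <- length(sel)
  }
  best
}
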