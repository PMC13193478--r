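#' Default synthetic-study configuration
#'
#' The generator defaults emulate the study conditions the analyses target:
#' a clade of a few hundred species with crown age c. 30 Myr, an epoch
#' boundary at 7 Ma, speciation initially structured by a hidden state and
#' trait-dependent afterwards (evergreen faster), transitions toward
#' deciduousness frequent early and nearly absent late, and the reverse
#' transition roughly constant.
#'
#' @param seed Integer seed.
#' @param n_tips Target extant tip count.
#' @param crown_age,slice_age Myr.
#' @param ... Overrides for any element.
#' @export
sim_config <- function(seed = 1, n_tips = 300, crown_age = 30,
                       slice_age = 7, ...) {
  cfg <- list(
    seed = seed, n_tips = n_tips, crown_age = crown_age,
    slice_age = slice_age,
    # rows: early, late; composite states (obs0,hA) (obs1,hA) (obs0,hB)
    # (obs1,hB).  Early: speciation varies by hidden state only; late: by
    # observed state (evergreen = obs0 faster).
    lambda = rbind(c(0.10, 0.10, 0.25, 0.25), c(0.45, 0.18, 0.45, 0.18)),
    mu = rbind(rep(0.03, 4), rep(0.05, 4)),
    q01 = c(0.113, 1e-4),   # evergreen -> deciduous, early/late
    q10 = c(0.015, 0.014),  # deciduous -> evergreen
    q_hidden = c(0.05, 0.05),
    root_state = 1L)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

sim_qflat <- function(cfg) {
  qflat <- numeric(32)
  for (e in 1:2) {
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- cfg$q01[e]; Q[3, 4] <- cfg$q01[e]
    Q[2, 1] <- cfg$q10[e]; Q[4, 3] <- cfg$q10[e]
    Q[1, 3] <- cfg$q_hidden[e]; Q[3, 1] <- cfg$q_hidden[e]
    Q[2, 4] <- cfg$q_hidden[e]; Q[4, 2] <- cfg$q_hidden[e]
    qflat[(e - 1) * 16 + 1:16] <- as.vector(t(Q))
  }
  qflat
}

#' Simulate a tree and binary trait under the time-sliced SSE process
#'
#' Gillespie forward simulation of the state-dependent birth-death process
#' over the four composite states, with the rate switch at `slice_age`;
#' extinct lineages are pruned from the returned tree.  Retries until the
#' extant tip count falls within `[0.5, 2] x n_tips`.
#'
#' @param cfg A [sim_config()].
#' @param max_tries Retry cap.
#' @return List: `tree` (extant, ultrametric), `states` (named observed 0/1),
#'   `composite_states`, `full_tree` (includes extinct tips), `events`
#'   (full event log), `tries`.
#' @export
simulate_sse_dataset <- function(cfg, max_tries = 500) {
  set.seed(cfg$seed)
  qflat <- sim_qflat(cfg)
  qm <- list(matrix(qflat[1:16], 4, 4, byrow = TRUE),
             matrix(qflat[17:32], 4, 4, byrow = TRUE))
  total_extinctions <- 0
  for (try in seq_len(max_tries)) {
    res <- sim_sse_once(cfg, qm)
    if (is.null(res)) {
      total_extinctions <- total_extinctions + 1
      if (total_extinctions >= 100)
        stop("100 consecutive total extinctions; increase speciation or ",
             "decrease extinction rates")
      next
    }
    n <- ape::Ntip(res$tree)
    if (n >= 0.5 * cfg$n_tips && n <= 2 * cfg$n_tips) {
      res$tries <- try
      return(res)
    }
  }
  stop("could not reach the target tip-count window in ", max_tries,
       " tries")
}

sim_sse_once <- function(cfg, qm) {
  T_end <- cfg$crown_age
  switch_s <- cfg$crown_age - cfg$slice_age  # forward time of epoch change
  epoch_at <- function(s) if (s < switch_s) 1L else 2L
  # lineage records
  id <- 2L
  lin <- list(t_start = c(0, 0), t_end = c(NA_real_, NA_real_),
              parent = c(0L, 0L), state = c(cfg$root_state, cfg$root_state),
              fate = c(NA_character_, NA_character_))
  active <- c(1L, 2L)
  st_active <- c(cfg$root_state, cfg$root_state)
  s <- 0
  events <- list()
  while (length(active) > 0 && s < T_end) {
    e <- epoch_at(s)
    lam <- cfg$lambda[e, ]; mu <- cfg$mu[e, ]; Q <- qm[[e]]
    rate_lin <- lam[st_active] + mu[st_active] + rowSums(Q)[st_active]
    R <- sum(rate_lin)
    if (R <= 0) break
    dt <- rexp(1, R)
    if (s < switch_s && s + dt > switch_s) { s <- switch_s; next }
    s <- s + dt
    if (s >= T_end) break
    i <- sample.int(length(active), 1, prob = rate_lin)
    li <- active[i]; st <- st_active[i]
    u <- runif(1) * rate_lin[i]
    if (u < lam[st]) { # speciation
      lin$t_end[li] <- s; lin$fate[li] <- "speciation"
      for (k in 1:2) {
        id <- id + 1L
        lin$t_start[id] <- s; lin$t_end[id] <- NA_real_
        lin$parent[id] <- li; lin$state[id] <- st
        lin$fate[id] <- NA_character_
      }
      active <- c(active[-i], id - 1L, id)
      st_active <- c(st_active[-i], st, st)
      events[[length(events) + 1]] <- list(time = s, type = "speciation",
                                           lineage = li, state = st)
    } else if (u < lam[st] + mu[st]) { # extinction
      lin$t_end[li] <- s; lin$fate[li] <- "extinction"
      active <- active[-i]; st_active <- st_active[-i]
      events[[length(events) + 1]] <- list(time = s, type = "extinction",
                                           lineage = li, state = st)
    } else { # state transition
      w <- Q[st, ]
      new_st <- sample.int(4, 1, prob = w)
      st_active[i] <- new_st
      lin$state[li] <- new_st
      events[[length(events) + 1]] <- list(time = s, type = "transition",
                                           lineage = li, from = st,
                                           to = new_st)
    }
    if (length(active) > 8 * cfg$n_tips) return(NULL) # runaway; retry
  }
  if (length(active) < 2) return(NULL)
  lin$t_end[active] <- T_end
  lin$fate[active] <- "extant"
  df <- data.frame(id = seq_len(id), t_start = lin$t_start[1:id],
                   t_end = lin$t_end[1:id], parent = lin$parent[1:id],
                   state = lin$state[1:id], fate = lin$fate[1:id])
  full <- lineages_to_phylo(df)
  extinct <- full$tip_lineage[df$fate[full$tip_lineage] == "extinction"]
  extinct_lab <- full$tree$tip.label[match(extinct, full$tip_lineage)]
  tree <- if (length(extinct_lab) > 0)
    ape::drop.tip(full$tree, extinct_lab) else full$tree
  if (is.null(tree) || ape::Ntip(tree) < 2) return(NULL)
  tip_lin <- full$tip_lineage[match(tree$tip.label, full$tree$tip.label)]
  comp <- setNames(df$state[tip_lin], tree$tip.label)
  obs <- setNames(as.integer((comp - 1) %% 2), tree$tip.label)
  ev <- do.call(rbind, lapply(events, function(x)
    data.frame(time = x$time, type = x$type, lineage = x$lineage,
               from = if (!is.null(x$from)) x$from else x$state,
               to = if (!is.null(x$to)) x$to else x$state)))
  list(tree = tree, states = obs, composite_states = comp,
       full_tree = full$tree, events = ev, lineages = df)
}

# build an ape phylo from lineage records (each lineage = one edge)
lineages_to_phylo <- function(df) {
  is_tip <- !(df$id %in% df$parent)
  tip_ids <- df$id[is_tip]
  int_ids <- df$id[!is_tip]
  n_tip <- length(tip_ids)
  # node numbers: tips 1..n_tip; root n_tip+1; internal lineages map to the
  # node created at their end (their speciation event)
  node_of_lineage <- integer(max(df$id))
  node_of_lineage[tip_ids] <- seq_len(n_tip)
  node_of_lineage[int_ids] <- n_tip + 1L + seq_along(int_ids)
  root_node <- n_tip + 1L
  parent_node <- ifelse(df$parent == 0L, root_node,
                        node_of_lineage[pmax(df$parent, 1L)])
  edge <- cbind(parent_node, node_of_lineage[df$id])
  elen <- df$t_end - df$t_start
  tree <- structure(list(edge = edge, edge.length = elen,
                         Nnode = length(int_ids) + 1L,
                         tip.label = paste0("t", seq_len(n_tip))),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree, tip_lineage = tip_ids)
}

#' Simulate a continuous trait along a painted tree (exact OU transitions)
#'
#' Samples tip (and node) values segment by segment with the exact Gaussian
#' transition `x' = theta + (x - theta) e^(-alpha t) + N(0, sigma^2 (1 -
#' e^(-2 alpha t)) / (2 alpha))`; the Brownian limit is used when alpha = 0.
#'
#' @param tree `phylo`.
#' @param map A `regime_map`.
#' @param sigma2,alpha,theta Length-2 per-regime parameters (regimes "0",
#'   "1").
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named tip values; node values in attribute `node_values`.
#' @export
simulate_ou_traits <- function(tree, map, sigma2, alpha, theta, root_value,
                               seed = 1) {
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  x <- numeric(n_node)
  x[n_tip + 1L] <- root_value
  pt <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(pt$edge)))
  edge_row <- match(paste(pt$edge[, 1], pt$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  for (i in pre) {
    par <- pt$edge[i, 1]; ch <- pt$edge[i, 2]
    segs <- map$maps[[edge_row[i]]]
    val <- x[par]
    for (s in seq_along(segs)) {
      r <- as.integer(names(segs)[s]) + 1L
      tt <- segs[[s]]
      a <- alpha[r]; s2 <- sigma2[r]; th <- theta[r]
      if (a > 1e-12) {
        e1 <- exp(-a * tt)
        val <- th + (val - th) * e1 +
          rnorm(1, 0, sqrt(s2 * (-expm1(-2 * a * tt)) / (2 * a)))
      } else {
        val <- val + rnorm(1, 0, sqrt(s2 * tt))
      }
    }
    x[ch] <- val
  }
  structure(setNames(x[seq_len(n_tip)], tree$tip.label),
            node_values = x[(n_tip + 1L):n_node])
}

#' Simulate a binary response from the phylogenetic multilevel model
#'
#' Draws predictors with controllable inter-predictor correlation,
#' phylogenetically correlated intercepts `a ~ MVN(0, sigma_phylo^2 C)`,
#' independent species effects, and Bernoulli responses through the logistic
#' link.
#'
#' @param tree `phylo` (defines C and the species set).
#' @param b0 Intercept.
#' @param beta Fixed-effect coefficients (length p).
#' @param sigma_phylo,sigma_species Random-effect SDs.
#' @param x_sd Predictor SD (default 0.5, mimicking 2-SD-scaled inputs).
#' @param x_corr Optional p x p predictor correlation matrix (or a single
#'   scalar applied to the first pair).
#' @param seed Integer seed.
#' @return List with `X`, `y`, `a`, `u`, `eta`, `C`.
#' @export
simulate_glmm_dataset <- function(tree, b0, beta, sigma_phylo,
                                  sigma_species, x_sd = 0.5, x_corr = NULL,
                                  seed = 1) {
  set.seed(seed)
  C <- phylo_correlation(tree)
  n <- nrow(C)
  p <- length(beta)
  R <- diag(p)
  if (!is.null(x_corr)) {
    if (is.matrix(x_corr)) R <- x_corr
    else if (p >= 2) { R[1, 2] <- R[2, 1] <- x_corr }
  }
  X <- matrix(rnorm(n * p), n, p) %*% chol(R) * x_sd
  rownames(X) <- rownames(C)
  colnames(X) <- paste0("x", seq_len(p))
  a <- as.vector(sigma_phylo * (t(chol(C + diag(1e-10, n))) %*% rnorm(n)))
  u <- rnorm(n, 0, sigma_species)
  eta <- b0 + as.vector(X %*% beta) + a + u
  y <- setNames(rbinom(n, 1, plogis(eta)), rownames(C))
  list(X = X, y = y, a = a, u = u, eta = eta, C = C)
}

#' Simulate occurrences, range polygons and environmental layers
#'
#' Smooth environmental gradients (linear trend plus a sinusoidal ripple and
#' optional white noise) on a regular grid; species get random convex range
#' polygons and clustered occurrence points inside them; a configurable
#' fraction of species receives fewer than five points to exercise the
#' random-point path.
#'
#' @param n_species Number of species.
#' @param extent `c(xmin, xmax, ymin, ymax)` degrees.
#' @param grid_res Grid resolution (degrees).
#' @param points_per_species Range of points for data-rich species.
#' @param frac_sparse Fraction of species given < 5 points.
#' @param noise_sd SD of white noise added to each layer (0 = smooth).
#' @param seed Integer seed.
#' @return List: `occ` (species, lon, lat), `polygons`, `grid`
#'   ([env_grid()] with AI, VPD, GSP, clay, sand), `centers`.
#' @export
simulate_occurrences <- function(n_species = 30,
                                 extent = c(-70, -40, -25, 0),
                                 grid_res = 0.25,
                                 points_per_species = c(8, 40),
                                 frac_sparse = 0.2, noise_sd = 0,
                                 seed = 1) {
  set.seed(seed)
  nx <- ceiling((extent[2] - extent[1]) / grid_res)
  ny <- ceiling((extent[4] - extent[3]) / grid_res)
  cx <- extent[1] + (seq_len(nx) - 0.5) * grid_res
  cy <- extent[3] + (seq_len(ny) - 0.5) * grid_res
  gx <- matrix(rep(cx, times = ny), nx, ny)
  gy <- matrix(rep(cy, each = nx), nx, ny)
  sx <- (gx - extent[1]) / (extent[2] - extent[1])
  sy <- (gy - extent[3]) / (extent[4] - extent[3])
  ripple <- function(f) sin(2 * pi * f * sx) * cos(2 * pi * f * sy)
  mk_layer <- function(base, xs, ys, amp, f)
    base + xs * sx + ys * sy + amp * ripple(f) +
      if (noise_sd > 0) matrix(rnorm(nx * ny, 0, noise_sd), nx, ny) else 0
  layers <- list(AI = mk_layer(0.2, 0.9, 0.3, 0.05, 1.5),
                 VPD = mk_layer(2.5, -1.5, -0.5, 0.1, 2),
                 GSP = mk_layer(300, 1200, 300, 50, 1),
                 clay = mk_layer(20, 15, -5, 2, 2.5),
                 sand = mk_layer(55, -20, 10, 3, 1.5))
  grid <- env_grid(extent[1], extent[3], grid_res, layers)
  occ <- list(); polygons <- list(); centers <- matrix(NA_real_, n_species, 2)
  n_sparse <- round(frac_sparse * n_species)
  for (i in seq_len(n_species)) {
    sp <- sprintf("sp%03d", i)
    ctr <- c(runif(1, extent[1] + 2, extent[2] - 2),
             runif(1, extent[3] + 2, extent[4] - 2))
    centers[i, ] <- ctr
    ang <- sort(runif(8, 0, 2 * pi))
    rad <- runif(8, 0.8, 2.5)
    ring <- cbind(lon = ctr[1] + rad * cos(ang),
                  lat = ctr[2] + rad * sin(ang))
    poly <- convex_hull(ring)
    polygons[[sp]] <- poly
    n_pts <- if (i <= n_sparse) sample(2:4, 1)
             else sample(points_per_species[1]:points_per_species[2], 1)
    pts <- matrix(NA_real_, 0, 2)
    guard <- 0
    while (nrow(pts) < n_pts && guard < 200) {
      cand <- cbind(rnorm(n_pts * 2, ctr[1], 0.7),
                    rnorm(n_pts * 2, ctr[2], 0.7))
      cand <- cand[point_in_polygon(cand, poly), , drop = FALSE]
      pts <- rbind(pts, cand)
      guard <- guard + 1
    }
    pts <- pts[seq_len(min(n_pts, nrow(pts))), , drop = FALSE]
    occ[[sp]] <- data.frame(species = sp, lon = pts[, 1], lat = pts[, 2])
  }
  list(occ = do.call(rbind, c(occ, list(make.row.names = FALSE))),
       polygons = polygons, grid = grid, centers = centers)
}
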