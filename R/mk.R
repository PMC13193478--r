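#' Two-state Markov (Mk) transition probability matrix
#'
#' Closed form for the binary-state continuous-time Markov chain with forward
#' rate `q01` (state 0 to 1) and backward rate `q10`.
#'
#' @param t Elapsed time (Myr).
#' @param q01,q10 Transition rates (per Myr), both `>= 0`.
#' @return 2x2 matrix, rows = starting state (0, 1).
#' @export
mk_prob <- function(t, q01, q10) {
  check_rates(q01, q10)
  r <- q01 + q10
  if (r == 0) return(diag(2))
  pi1 <- q01 / r
  e <- exp(-r * t)
  matrix(c(1 - pi1 + pi1 * e, pi1 - pi1 * e,
           (1 - pi1) - (1 - pi1) * e, pi1 + (1 - pi1) * e),
         nrow = 2, byrow = TRUE)
}

check_rates <- function(q01, q10) {
  if (q01 < 0 || q10 < 0) stop("transition rates must be non-negative")
  invisible(TRUE)
}

resolve_root_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != 2 || any(root_prior < 0))
      stop("numeric root prior must be a length-2 non-negative vector")
    return(root_prior / sum(root_prior))
  }
  root_prior <- match.arg(root_prior, c("flat", "stationary"))
  if (root_prior == "flat") return(c(0.5, 0.5))
  r <- q01 + q10
  if (r == 0) return(c(0.5, 0.5))
  c(q10, q01) / r
}

# postorder conditional likelihoods; returns list(L, logscale, post_tree)
mk_downpass <- function(tree, states, q01, q10) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  L <- matrix(0, n_node, 2)
  L[cbind(seq_len(n_tip), states[tree$tip.label] + 1L)] <- 1
  pt <- ape::reorder.phylo(tree, "postorder")
  logscale <- 0
  # accumulate child messages into parents
  M <- matrix(1, n_node, 2)
  for (e in seq_len(nrow(pt$edge))) {
    par <- pt$edge[e, 1]; ch <- pt$edge[e, 2]
    if (ch > n_tip) {
      L[ch, ] <- M[ch, ]
      sc <- sum(L[ch, ])
      if (sc <= 0) return(list(L = L, logscale = -Inf))
      L[ch, ] <- L[ch, ] / sc
      logscale <- logscale + log(sc)
    }
    P <- mk_prob(pt$edge.length[e], q01, q10)
    M[par, ] <- M[par, ] * as.vector(P %*% L[ch, ])
  }
  root <- n_tip + 1L
  L[root, ] <- M[root, ]
  sc <- sum(L[root, ])
  if (sc <= 0) return(list(L = L, logscale = -Inf))
  L[root, ] <- L[root, ] / sc
  logscale <- logscale + log(sc)
  list(L = L, logscale = logscale)
}

#' Mk model log-likelihood for a binary trait
#'
#' Felsenstein pruning with the closed-form 2x2 transition probabilities.
#' Used both directly (ARD transition-rate fitting, stochastic mapping) and
#' as the trait-evolution component oracle for the SSE machinery.
#'
#' @param tree A `phylo` object.
#' @param states Named integer vector (0/1) covering every tip.
#' @param q01,q10 Transition rates (per Myr).
#' @param root_prior `"flat"` (default), `"stationary"`, or a length-2
#'   probability vector.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, q01, q10, root_prior = "flat") {
  states <- check_states(tree, states)
  check_rates(q01, q10)
  dp <- mk_downpass(tree, states, q01, q10)
  if (!is.finite(dp$logscale)) return(-Inf)
  pi0 <- resolve_root_prior(root_prior, q01, q10)
  root <- ape::Ntip(tree) + 1L
  log(sum(pi0 * dp$L[root, ])) + dp$logscale
}

check_states <- function(tree, states) {
  if (is.null(names(states))) stop("`states` must be named by tip label")
  if (!all(tree$tip.label %in% names(states)))
    stop("missing states for tips: ",
         paste(head(setdiff(tree$tip.label, names(states))), collapse = ", "))
  states <- states[tree$tip.label]
  if (anyNA(states) || !all(states %in% c(0, 1)))
    stop("tip states must be 0 or 1 with no missing values")
  storage.mode(states) <- "integer"
  states
}

#' Fit the all-rates-different (ARD) Mk model by maximum likelihood
#'
#' Bounded quasi-Newton optimization on log rates with multiple starting
#' points (reproducible under `seed`).
#'
#' @inheritParams mk_loglik
#' @param n_starts Number of optimizer starts.
#' @param seed Integer seed for the start draws.
#' @param lower,upper Rate bounds (per Myr).
#' @return List with `q01`, `q10`, `loglik`, `starts` (per-start records).
#' @export
fit_mk_ard <- function(tree, states, root_prior = "flat", n_starts = 5,
                       seed = 1, lower = 1e-9, upper = 100) {
  states <- check_states(tree, states)
  tab <- table(factor(states, levels = 0:1))
  if (any(tab < 2))
    warning("fewer than 2 tips in state ",
            paste(names(tab)[tab < 2], collapse = ","),
            "; rate estimates may sit on a boundary", call. = FALSE)
  h <- tree_height(tree)
  nll <- function(lp) {
    ll <- mk_loglik(tree, states, exp(lp[1]), exp(lp[2]), root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  starts <- matrix(log(1 / h) + log(c(0.5, 2)[sample.int(2, 2 * n_starts,
                                                         replace = TRUE)]) +
                     rnorm(2 * n_starts, 0, 1), ncol = 2)
  runs <- lapply(seq_len(n_starts), function(i) {
    fit <- nlminb(starts[i, ], nll, lower = log(lower), upper = log(upper))
    list(par = exp(fit$par), loglik = -fit$objective,
         convergence = fit$convergence)
  })
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  list(q01 = best$par[1], q10 = best$par[2], loglik = best$loglik,
       starts = runs)
}

#' Marginal ancestral-state posteriors under the Mk model
#'
#' Joint down-pass/up-pass computation of `P(state at node | tip data)` for
#' every node; the pruning-based oracle against which stochastic maps are
#' checked.
#'
#' @inheritParams mk_loglik
#' @return Matrix (nodes x 2) of posterior state probabilities, rows ordered
#'   by ape node number (tips first).
#' @export
mk_marginal_states <- function(tree, states, q01, q10, root_prior = "flat") {
  states <- check_states(tree, states)
  dp <- mk_downpass(tree, states, q01, q10)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  pi0 <- resolve_root_prior(root_prior, q01, q10)
  # up-pass: U[v,s] = (scaled) likelihood of data outside v's subtree
  U <- matrix(0, n_node, 2)
  U[root, ] <- pi0
  pt <- ape::reorder.phylo(tree, "postorder")
  children <- split(pt$edge[, 2], pt$edge[, 1])
  elen <- setNames(pt$edge.length, pt$edge[, 2])
  for (v in rev(unique(pt$edge[, 1]))) {  # preorder over internal nodes
    kids <- children[[as.character(v)]]
    msg <- lapply(kids, function(c)
      as.vector(mk_prob(elen[[as.character(c)]], q01, q10) %*% dp$L[c, ]))
    for (i in seq_along(kids)) {
      sib <- Reduce(`*`, msg[-i], rep(1, 2))
      above <- U[v, ] * sib
      c <- kids[i]
      U[c, ] <- as.vector(t(mk_prob(elen[[as.character(c)]], q01, q10)) %*%
                            above)
      sc <- sum(U[c, ])
      if (sc > 0) U[c, ] <- U[c, ] / sc
    }
  }
  post <- dp$L * U
  post / rowSums(post)
}

#' Stochastic character maps under a fixed Mk model
#'
#' Samples complete binary-trait histories consistent with the tip data:
#' node states are drawn from their joint conditional distribution (pruning
#' based), then within-branch histories are simulated by rejection
#' conditioned on the branch endpoints.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps to draw.
#' @param seed Integer seed.
#' @param reject_cap Maximum rejection attempts per branch before erroring.
#' @return A list of `regime_map` objects.  Each has `maps`: per edge (row
#'   order of `tree$edge`) a named numeric vector of segment durations, names
#'   `"0"`/`"1"`, ordered parent to child and summing to the branch length;
#'   and `node_states`: state at every node.
#' @export
stochastic_maps <- function(tree, states, q01, q10, n_maps = 100,
                            root_prior = "flat", seed = 1,
                            reject_cap = 1e5) {
  stopifnot(n_maps >= 1)
  states <- check_states(tree, states)
  dp <- mk_downpass(tree, states, q01, q10)
  if (!is.finite(dp$logscale))
    stop("tip data have zero likelihood under the supplied rates")
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  pi0 <- resolve_root_prior(root_prior, q01, q10)
  pt <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(pt$edge)))
  set.seed(seed)
  Pcache <- lapply(seq_len(nrow(pt$edge)), function(e)
    mk_prob(pt$edge.length[e], q01, q10))
  edge_row <- match(paste(pt$edge[, 1], pt$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  lapply(seq_len(n_maps), function(m) {
    ns <- integer(n_tip + tree$Nnode)
    w <- pi0 * dp$L[root, ]
    ns[root] <- sample.int(2, 1, prob = w) - 1L
    maps <- vector("list", nrow(tree$edge))
    for (e in pre) {
      par <- pt$edge[e, 1]; ch <- pt$edge[e, 2]
      w <- Pcache[[e]][ns[par] + 1L, ] * dp$L[ch, ]
      ns[ch] <- sample.int(2, 1, prob = w) - 1L
      maps[[edge_row[e]]] <- simulate_branch_path(
        ns[par], ns[ch], pt$edge.length[e], q01, q10, reject_cap)
    }
    structure(list(tree = tree, maps = maps, node_states = ns),
              class = "regime_map")
  })
}

# conditioned CTMC path on one branch by rejection; returns named durations
simulate_branch_path <- function(a, b, t, q01, q10, cap) {
  rates <- c(q01, q10)
  if (t <= 0) {
    if (a != b) stop("zero-length branch with differing endpoint states")
    return(setNames(t, as.character(a)))
  }
  for (attempt in seq_len(cap)) {
    s <- a
    times <- numeric(0)
    tcur <- 0
    repeat {
      r <- rates[s + 1L]
      if (r <= 0) break
      dt <- rexp(1, r)
      if (tcur + dt >= t) break
      tcur <- tcur + dt
      times <- c(times, tcur)
      s <- 1L - s
    }
    if (s == b) {
      bounds <- c(0, times, t)
      segs <- diff(bounds)
      st <- rep(c(a, 1L - a), length.out = length(segs))
      return(setNames(segs, as.character(st)))
    }
  }
  stop("rejection cap (", cap, ") exceeded on a branch; increase the cap ",
       "or check the transition rates")
}

#' Count state transitions in a regime map
#' @param map A `regime_map`.
#' @export
count_transitions <- function(map) {
  sum(vapply(map$maps, function(m) length(m) - 1L, integer(1)))
}
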