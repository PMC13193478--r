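#' The nine-model family of niche-evolution models
#'
#' Brownian-motion and Ornstein-Uhlenbeck models of a continuous
#' environmental-niche trait under two selective regimes (evergreen = "0",
#' deciduous = "1") painted on the tree.  Model names follow the field's
#' convention: `V` lets the diffusion rate sigma^2 vary by regime, `A` the
#' selection strength alpha, `M` the optimum theta; `BM*` models have
#' alpha = 0.
#'
#' @param name One of `"BM1"`, `"BMV"`, `"OU1"`, `"OUA"`, `"OUV"`, `"OUM"`,
#'   `"OUVA"`, `"OUMV"`, `"OUMVA"`.
#' @return An `ou_spec` with the vary flags, free-parameter names and count.
#' @export
ou_model_spec <- function(name) {
  name <- match.arg(name, c("BM1", "BMV", "OU1", "OUA", "OUV", "OUM",
                            "OUVA", "OUMV", "OUMVA"))
  is_ou <- startsWith(name, "OU")
  suffix <- sub("^(BM|OU)", "", name)
  vary_sigma <- grepl("V", suffix) || suffix == "V"
  vary_alpha <- is_ou && grepl("A", suffix)
  vary_theta <- is_ou && grepl("M", suffix)
  pn <- c(if (vary_sigma) c("sigma2_0", "sigma2_1") else "sigma2",
          if (is_ou) { if (vary_alpha) c("alpha_0", "alpha_1") else "alpha" },
          if (is_ou) { if (vary_theta) c("theta_0", "theta_1") else "theta" },
          if (!is_ou) "z0")
  structure(list(name = name, is_ou = is_ou, vary_sigma = vary_sigma,
                 vary_alpha = vary_alpha, vary_theta = vary_theta,
                 par_names = pn, k = length(pn)),
            class = "ou_spec")
}

#' @rdname ou_model_spec
#' @export
ou_model_names <- function() {
  c("BM1", "BMV", "OU1", "OUA", "OUV", "OUM", "OUVA", "OUMV", "OUMVA")
}

# named free pars -> per-regime sigma2/alpha/theta (length-2) + root mean
ou_resolve_params <- function(spec, par) {
  p <- as.list(par)
  sigma2 <- if (spec$vary_sigma) c(p$sigma2_0, p$sigma2_1) else rep(p$sigma2, 2)
  alpha <- if (!spec$is_ou) c(0, 0)
           else if (spec$vary_alpha) c(p$alpha_0, p$alpha_1)
           else rep(p$alpha, 2)
  theta <- if (!spec$is_ou) c(0, 0)
           else if (spec$vary_theta) c(p$theta_0, p$theta_1)
           else rep(p$theta, 2)
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (any(alpha < 0)) stop("alpha must be non-negative")
  list(sigma2 = sigma2, alpha = alpha, theta = theta,
       z0 = if (!spec$is_ou) p$z0 else NULL)
}

# flatten a regime map into preorder segment arrays for the C++ kernel
ou_flatten_map <- function(map, cache) {
  ne <- nrow(cache$pre_edges)
  seg_count <- integer(ne)
  regs <- durs <- vector("list", ne)
  for (i in seq_len(ne)) {
    segs <- map$maps[[cache$pre_rows[i]]]
    seg_count[i] <- length(segs)
    regs[[i]] <- as.integer(names(segs))
    durs[[i]] <- as.numeric(segs)
  }
  basal <- which(cache$pre_edges[, 1] == cache$n_tip + 1L)[1]
  list(seg_count = seg_count, seg_regime = unlist(regs),
       seg_dur = unlist(durs),
       root_regime = as.integer(names(map$maps[[cache$pre_rows[basal]]])[1]))
}

# geometry shared across likelihood evaluations on one tree
ou_tree_cache <- function(tree) {
  n_tip <- ape::Ntip(tree)
  M <- ape::mrca(tree)
  pt <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(pt$edge)))
  edge_row <- match(paste(pt$edge[, 1], pt$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  list(n_tip = n_tip, n_node = n_tip + tree$Nnode, mrca = M,
       pre_edges = pt$edge[pre, , drop = FALSE],
       pre_rows = edge_row[pre], tip_label = tree$tip.label)
}

#' Gaussian tip moments under a painted BM/OU model
#'
#' Propagates the expectation and variance of the trait along every branch
#' with segment-wise constant (alpha, sigma^2, theta) taken from a regime
#' map, giving the exact multivariate-Gaussian tip distribution.  The tip
#' covariance of two species is the variance accumulated at their MRCA,
#' attenuated by `exp(-integral of alpha)` along each descending path.
#'
#' @param tree A `phylo` object.
#' @param map A `regime_map` covering the tree (see [stochastic_maps()]).
#' @param spec An [ou_model_spec()].
#' @param par Named free-parameter vector.
#' @param root `"theta"` (OU models start at the root regime's optimum, the
#'   default), `"stationary"` (stationary variance at the root), or for BM
#'   models the estimated ancestral mean `z0` is used.
#' @param cache Optional precomputed [ou_tree_cache()].
#' @return List with `mean` (named tip vector) and `cov` (tip matrix).
#' @export
ou_tip_moments <- function(tree, map, spec, par, root = "theta",
                           cache = NULL) {
  if (is.null(cache)) cache <- ou_tree_cache(tree)
  rp <- ou_resolve_params(spec, par)
  n_node <- cache$n_node
  m <- v <- la <- numeric(n_node)
  root_node <- cache$n_tip + 1L
  # root regime: the state at the start of any basal branch
  basal <- which(cache$pre_edges[, 1] == root_node)[1]
  rr <- as.integer(names(map$maps[[cache$pre_rows[basal]]])[1]) + 1L
  if (spec$is_ou) {
    m[root_node] <- rp$theta[rr]
    v[root_node] <- if (identical(root, "stationary"))
      rp$sigma2[rr] / (2 * rp$alpha[rr]) else 0
  } else {
    m[root_node] <- rp$z0
    v[root_node] <- 0
  }
  for (i in seq_len(nrow(cache$pre_edges))) {
    par_n <- cache$pre_edges[i, 1]; ch <- cache$pre_edges[i, 2]
    segs <- map$maps[[cache$pre_rows[i]]]
    mm <- m[par_n]; vv <- v[par_n]; ll <- la[par_n]
    regs <- as.integer(names(segs)) + 1L
    for (s in seq_along(segs)) {
      r <- regs[s]; tt <- segs[[s]]
      a <- rp$alpha[r]; s2 <- rp$sigma2[r]
      if (a > 1e-12) {
        e1 <- exp(-a * tt)
        mm <- rp$theta[r] + (mm - rp$theta[r]) * e1
        vv <- vv * e1 * e1 + s2 * (-expm1(-2 * a * tt)) / (2 * a)
        ll <- ll - a * tt
      } else {
        vv <- vv + s2 * tt
      }
    }
    m[ch] <- mm; v[ch] <- vv; la[ch] <- ll
  }
  tips <- seq_len(cache$n_tip)
  M <- cache$mrca
  S <- v[M] * exp(outer(la[tips], la[tips], `+`) - 2 * la[M])
  diag(S) <- v[tips]
  dimnames(S) <- list(cache$tip_label, cache$tip_label)
  list(mean = setNames(m[tips], cache$tip_label), cov = S)
}

# multivariate normal log density via Cholesky; ridged on singularity
dmvnorm_log <- function(x, mean, cov, ridge = 1e-10) {
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular tip covariance; adding ridge ", ridge, call. = FALSE)
    ch <- chol(cov + diag(ridge, nrow(cov)))
  }
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z * z))
}

log_mean_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(mean(exp(x - mx)))
}

#' Map-averaged niche-model log-likelihood
#'
#' Per-map multivariate-Gaussian log density from [ou_tip_moments()],
#' combined across stochastic maps by log-mean-exp (the likelihood averaged
#' over the discrete-history posterior).
#'
#' @inheritParams ou_tip_moments
#' @param maps List of `regime_map`s.
#' @param x Named per-species trait values (standardized environmental
#'   variable).
#' @export
niche_loglik <- function(tree, maps, x, spec, par, root = "theta",
                         cache = NULL) {
  if (inherits(maps, "regime_map")) maps <- list(maps)
  if (is.null(cache)) cache <- ou_tree_cache(tree)
  if (is.null(names(x))) stop("`x` must be named by species")
  x <- x[cache$tip_label]
  if (anyNA(x)) stop("trait values missing for some tips")
  flat <- lapply(maps, function(mp) {
    if (inherits(mp, "regime_map")) ou_flatten_map(mp, cache) else mp
  })
  rp <- ou_resolve_params(spec, par)
  lls <- vapply(flat, function(fm) {
    ou_map_loglik_cpp(cache$pre_edges, fm$seg_count, fm$seg_regime,
                      fm$seg_dur, cache$mrca, cache$n_tip, cache$n_node,
                      fm$root_regime, rp$sigma2, rp$alpha, rp$theta,
                      if (is.null(rp$z0)) 0 else rp$z0, spec$is_ou,
                      identical(root, "stationary"), as.numeric(x), 1e-10)
  }, numeric(1))
  log_mean_exp(lls)
}

#' Fit one niche-evolution model over fixed stochastic maps
#'
#' ML over the continuous parameters with the regime maps held fixed (the
#' two-step approximation: maps are shared across all compared models so the
#' AICc contrast isolates the continuous process).  Optimization is bounded
#' quasi-Newton on log sigma^2 / log alpha.
#'
#' @inheritParams niche_loglik
#' @param n_starts Optimizer starts (default 3).
#' @param seed Seed for start perturbations.
#' @return A `niche_fit`: `spec`, `par`, `loglik`, `k`, `n`, `AICc`,
#'   `usable` (FALSE when n <= k + 1), `starts`.
#' @export
fit_niche_model <- function(tree, maps, x, spec, root = "theta",
                            n_starts = 3, seed = 1, cache = NULL) {
  if (inherits(maps, "regime_map")) maps <- list(maps)
  if (is.null(cache)) cache <- ou_tree_cache(tree)
  maps <- lapply(maps, function(mp) {
    if (inherits(mp, "regime_map")) ou_flatten_map(mp, cache) else mp
  })
  x <- x[cache$tip_label]
  n <- length(x)
  h <- tree_height(tree)
  vlog <- startsWith(spec$par_names, "sigma2") |
    startsWith(spec$par_names, "alpha")
  base <- vapply(spec$par_names, function(nm) {
    if (startsWith(nm, "sigma2")) var(x) / h
    else if (startsWith(nm, "alpha")) 1 / h
    else mean(x)
  }, numeric(1))
  lower <- ifelse(vlog, log(1e-10), -1e3)
  upper <- ifelse(vlog, log(1e4), 1e3)
  to_nat <- function(p) ifelse(vlog, exp(p), p)
  nll <- function(p) {
    par <- setNames(to_nat(p), spec$par_names)
    ll <- tryCatch(suppressWarnings(
      niche_loglik(tree, maps, x, spec, par, root = root, cache = cache)),
      error = function(e) NA_real_)
    if (is.na(ll) || !is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  runs <- lapply(seq_len(n_starts), function(i) {
    p0 <- base
    p0[vlog] <- log(base[vlog])
    if (i > 1) p0 <- p0 + rnorm(length(p0), 0, 1)
    fit <- tryCatch(nlminb(p0, nll, lower = lower, upper = upper,
                           control = list(eval.max = 2000, iter.max = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(loglik = -Inf))
    list(par = setNames(to_nat(fit$par), spec$par_names),
         loglik = -fit$objective, convergence = fit$convergence)
  })
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls))) stop("optimizer diverged for model ", spec$name)
  best <- runs[[which.max(lls)]]
  k <- spec$k
  aicc <- if (n - k - 1 > 0)
    2 * k - 2 * best$loglik + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(spec = spec, par = best$par, loglik = best$loglik, k = k,
                 n = n, AICc = aicc, usable = n > k + 1, starts = runs),
            class = "niche_fit")
}

#' Fit and rank all nine niche-evolution models
#'
#' @inheritParams fit_niche_model
#' @return List with `fits` (named) and `table` (AICc ranking with Akaike
#'   weights over the usable models).
#' @export
fit_niche_models <- function(tree, maps, x, root = "theta", n_starts = 3,
                             seed = 1, cache = NULL) {
  if (is.null(cache)) cache <- ou_tree_cache(tree)
  fits <- lapply(ou_model_names(), function(nm)
    fit_niche_model(tree, maps, x, ou_model_spec(nm), root = root,
                    n_starts = n_starts, seed = seed, cache = cache))
  names(fits) <- ou_model_names()
  list(fits = fits, table = compare_niche_models(fits))
}

#' AICc comparison table for niche-model fits
#'
#' @param fits List of `niche_fit`s on identical data.
#' @return data.frame with `model`, `logL`, `k`, `AICc`, `dAICc`, `AICw`
#'   sorted ascending by AICc; models with `n <= k + 1` are flagged unusable
#'   and excluded from the weights.
#' @export
compare_niche_models <- function(fits) {
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) stop("fits are not on identical data")
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    logL = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    usable = vapply(fits, `[[`, logical(1), "usable"))
  tab$dAICc <- tab$AICc - min(tab$AICc[tab$usable])
  w <- ifelse(tab$usable, exp(-tab$dAICc / 2), 0)
  tab$AICw <- w / sum(w)
  tab[order(tab$AICc), , drop = FALSE]
}

#' Niche-evolution model selection for several environmental variables
#'
#' The full two-step analysis: fit ARD Mk transition rates for the regime
#' trait, draw stochastic maps once (shared across all models and
#' variables), z-score each environmental variable across species, and rank
#' the nine models per variable.
#'
#' @param tree Ultrametric `phylo`.
#' @param states Named 0/1 regime vector (evergreen = 0, deciduous = 1).
#' @param env data.frame with a `species` column and one column per
#'   environmental variable.
#' @param variables Character vector of env column names.
#' @param n_maps Number of stochastic maps (default 100).
#' @param seed Integer seed.
#' @param n_starts Optimizer starts per model.
#' @return Named list per variable, each as [fit_niche_models()].
#' @export
niche_model_selection <- function(tree, states, env, variables,
                                  n_maps = 100, seed = 1, n_starts = 3) {
  keep <- intersect(tree$tip.label, env$species)
  tr <- prune_tips(tree, setdiff(tree$tip.label, keep))
  st <- states[tr$tip.label]
  mk <- fit_mk_ard(tr, st, seed = seed)
  maps <- stochastic_maps(tr, st, mk$q01, mk$q10, n_maps = n_maps,
                          seed = seed)
  cache <- ou_tree_cache(tr)
  res <- lapply(variables, function(v) {
    x <- setNames(env[[v]], env$species)[tr$tip.label]
    x <- as.numeric(scale(x))
    names(x) <- tr$tip.label
    fit_niche_models(tr, maps, x, n_starts = n_starts, seed = seed,
                     cache = cache)
  })
  names(res) <- variables
  attr(res, "mk_fit") <- mk
  res
}
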