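#' Time-stratified SSE log-likelihood
#'
#' Integrates the standard D/E ordinary differential equations for the four
#' composite states along every branch from the tips to the root, switching
#' rate regimes at the epoch boundary (always an integration breakpoint, with
#' D and E continuous across it).  Speciation events multiply daughter D
#' vectors by the epoch's speciation rate; tips are initialized with the
#' per-observed-state sampling fraction.
#'
#' @param tree Ultrametric `phylo` object.
#' @param states Named 0/1 vector over all tips.
#' @param spec An [sse_model_spec()].
#' @param par Named free-rate vector (see `spec$par_names`), or a list with
#'   full arrays `lambda`, `mu`, `qflat` as from [sse_expand_params()].
#' @param root_weighting `"weighted"` (root states weighted by their
#'   normalized D values, the default) or `"flat"`.
#' @param condition_surv Condition the likelihood on two surviving crown
#'   lineages (default `TRUE`).
#' @param rtol,atol Integrator tolerances.
#' @param geometry Optional precomputed [sse_tree_geometry()] (cached by the
#'   fitting routines).
#' @return Log-likelihood with attribute `clip_count` (number of negative-D
#'   clippings; 0 in healthy runs).
#' @export
sse_loglik <- function(tree, states, spec, par,
                       root_weighting = c("weighted", "flat"),
                       condition_surv = TRUE, rtol = 1e-8, atol = 1e-10,
                       geometry = NULL) {
  root_weighting <- match.arg(root_weighting)
  states <- check_states(tree, states)
  arrays <- if (is.numeric(par)) sse_expand_params(spec, par) else par
  geom <- if (is.null(geometry)) sse_tree_geometry(tree) else geometry
  slice <- if (spec$sliced) spec$slice_age else -1
  res <- sse_loglik_cpp(geom$edge, geom$n_tip, geom$node_age,
                        as.integer(states),
                        arrays$lambda, arrays$mu, arrays$qflat, slice,
                        as.numeric(spec$sampling_fraction),
                        ifelse(root_weighting == "weighted", 1L, 0L),
                        condition_surv, rtol, atol)
  structure(res$loglik, clip_count = res$clip_count)
}

#' Precompute the branch geometry used by the SSE likelihood
#' @param tree Ultrametric `phylo`.
#' @export
sse_tree_geometry <- function(tree) {
  n_tip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  h <- max(depth[seq_len(n_tip)])
  age <- pmax(h - depth, 0)
  list(edge = tree$edge, n_tip = n_tip, node_age = age, height = h)
}

#' Fit a time-stratified SSE model by maximum likelihood
#'
#' Bounded quasi-Newton optimization on log-transformed rates with
#' Latin-hypercube starting points (reproducible under `seed`).  All starts
#' are recorded for multimodality diagnosis; the best is returned.
#'
#' @inheritParams sse_loglik
#' @param n_starts Number of optimizer starts (the analysis default is 2).
#' @param seed Integer seed for the start draws.
#' @param lower,upper Rate bounds (per Myr).
#' @param eval_max,iter_max Optimizer budget per start.
#' @return An `sse_fit`: `spec`, ML `par`, `loglik`, `k`, `AIC`, `starts`.
#' @export
fit_sse <- function(tree, states, spec, n_starts = 2, seed = 1,
                    root_weighting = "weighted", condition_surv = TRUE,
                    lower = 1e-6, upper = 10, rtol = 1e-8, atol = 1e-10,
                    eval_max = 2000, iter_max = 1000) {
  stopifnot(n_starts >= 1)
  states <- check_states(tree, states)
  k <- spec$k
  geom <- sse_tree_geometry(tree)
  nll <- function(lp) {
    ll <- sse_loglik(tree, states, spec,
                     setNames(exp(lp), spec$par_names),
                     root_weighting = root_weighting,
                     condition_surv = condition_surv, rtol = rtol,
                     atol = atol, geometry = geom)
    if (!is.finite(ll)) 1e10 else -as.numeric(ll)
  }
  starts <- sse_start_points(tree, states, spec, n_starts, seed)
  runs <- lapply(seq_len(n_starts), function(i) {
    fit <- tryCatch(
      nlminb(log(starts[i, ]), nll, lower = log(lower), upper = log(upper),
             control = list(eval.max = eval_max, iter.max = iter_max)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(loglik = -Inf, convergence = 1L,
                                  par = starts[i, ]))
    list(par = setNames(exp(fit$par), spec$par_names),
         loglik = -fit$objective, convergence = fit$convergence)
  })
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls)))
    stop("all optimizer starts failed; traces: ",
         paste(vapply(runs, function(r) format(r$loglik), character(1)),
               collapse = ", "))
  best <- runs[[which.max(lls)]]
  structure(list(spec = spec, par = best$par, loglik = best$loglik, k = k,
                 AIC = 2 * k - 2 * best$loglik, starts = runs,
                 data_id = sse_data_id(tree, states)),
            class = "sse_fit")
}

sse_start_points <- function(tree, states, spec, n_starts, seed) {
  h <- tree_height(tree)
  n <- ape::Ntip(tree)
  lam0 <- max((log(n) - log(2)) / h, 1e-3)
  lo <- hi <- numeric(spec$k)
  for (j in seq_len(spec$k)) {
    nm <- spec$par_names[j]
    if (startsWith(nm, "lambda")) { lo[j] <- lam0 * 0.2; hi[j] <- lam0 * 5 }
    else if (startsWith(nm, "mu")) { lo[j] <- lam0 * 0.01; hi[j] <- lam0 }
    else { lo[j] <- 0.1 / h; hi[j] <- 10 / h }
  }
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, spec$k)
  t(apply(u, 1, function(r) exp(log(lo) + r * (log(hi) - log(lo)))))
}

sse_data_id <- function(tree, states) {
  list(n_tip = ape::Ntip(tree),
       total_bl = signif(sum(tree$edge.length), 12),
       states = paste(states[tree$tip.label], collapse = ""))
}

#' Rank SSE fits by AIC
#'
#' @param fits List of `sse_fit` objects on the same data.
#' @return data.frame with `model`, `logL`, `k`, `AIC`, `dAIC`, `AICw`
#'   (weights summing to 1), sorted by AIC.
#' @export
compare_sse_models <- function(fits) {
  if (inherits(fits, "sse_fit")) fits <- list(fits)
  ids <- lapply(fits, `[[`, "data_id")
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("fits were computed on different datasets")
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    logL = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"))
  tab$AIC <- 2 * tab$k - 2 * tab$logL
  tab$dAIC <- tab$AIC - min(tab$AIC)
  w <- exp(-tab$dAIC / 2)
  tab$AICw <- w / sum(w)
  tab[order(tab$AIC), , drop = FALSE]
}

#' Fit the whole epoch-scenario model set and rank it
#'
#' @inheritParams fit_sse
#' @param slice_age Epoch boundary (Ma).
#' @param sampling_fraction Length-2 sampling fractions.
#' @return List with `fits` (named list of `sse_fit`), `table` (AIC ranking)
#'   and `best` (the top fit).
#' @export
fit_sse_model_set <- function(tree, states, slice_age,
                              sampling_fraction = c(0.6, 0.6),
                              n_starts = 2, seed = 1, ...) {
  specs <- build_model_set(slice_age, sampling_fraction)
  fits <- lapply(seq_along(specs), function(i)
    fit_sse(tree, states, specs[[i]], n_starts = n_starts,
            seed = seed + i, ...))
  names(fits) <- names(specs)
  tab <- compare_sse_models(fits)
  list(fits = fits, table = tab, best = fits[[tab$model[1]]])
}

#' Per-epoch rate summary of an SSE fit
#'
#' Observed-state transition rates and speciation rates for the early and
#' late epochs of a fitted model.  For epochs with trait-independent
#' speciation the two hidden-state rates are averaged, flagged by `mode`.
#'
#' @param fit An `sse_fit`.
#' @return data.frame with one row per epoch.
#' @export
sse_rate_summary <- function(fit) {
  spec <- fit$spec
  arr <- sse_expand_params(spec, fit$par)
  epochs <- c("early", "late")
  do.call(rbind, lapply(1:2, function(e) {
    lam <- arr$lambda[e, ]
    mode <- if (!spec$sliced) spec$early_mode
            else c(spec$early_mode, spec$late_mode)[e]
    Q <- matrix(arr$qflat[(e - 1) * 16 + 1:16], 4, 4, byrow = TRUE)
    data.frame(epoch = epochs[e], mode = mode,
               lambda_evergreen = mean(lam[c(1, 3)]),
               lambda_deciduous = mean(lam[c(2, 4)]),
               mu = arr$mu[e, 1],
               q_ED = Q[1, 2], q_DE = Q[2, 1], q_hidden = Q[1, 3])
  }))
}
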