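#' Specify the Bayesian phylogenetic multilevel Bernoulli model
#'
#' logit P(y_i = 1) = b0 + X_i beta + a_i + u_i with a ~ MVN(0,
#' sigma_phylo^2 C) for the phylogenetic correlation matrix C and u_i ~
#' N(0, sigma_species^2) an independent species-level intercept.  Fixed
#' effects get Normal(0, 2) priors; the intercept a Student-t(3, 0, 2.5);
#' the random-effect SDs half-t(3, 0, 2.5).
#'
#' @param predictors Ordered predictor names (columns of `X`).
#' @param prior_beta_sd Normal prior SD for fixed effects (default 2).
#' @param prior_t_df,prior_t_scale Student-t prior for the intercept and the
#'   random-effect SDs (default df 3, scale 2.5).
#' @param include_phylo,include_species_iid Random-effect switches.
#' @export
glmm_spec <- function(predictors, prior_beta_sd = 2, prior_t_df = 3,
                      prior_t_scale = 2.5, include_phylo = TRUE,
                      include_species_iid = TRUE) {
  stopifnot(length(predictors) >= 1)
  structure(list(predictors = as.character(predictors),
                 prior_beta_sd = prior_beta_sd, prior_t_df = prior_t_df,
                 prior_t_scale = prior_t_scale,
                 include_phylo = include_phylo,
                 include_species_iid = include_species_iid),
            class = "glmm_spec")
}

#' Assemble aligned response, predictors and phylogenetic correlation
#'
#' @param y Named binary response (1 = deciduous) per species.
#' @param X Predictor matrix (rows named by species), already 2-SD scaled.
#' @param C Phylogenetic correlation matrix (unit diagonal, PSD) with
#'   matching dimnames.
#' @export
glmm_data <- function(y, X, C) {
  X <- as.matrix(X)
  sp <- names(y)
  if (is.null(sp) || is.null(rownames(X)) || is.null(rownames(C)))
    stop("y, X and C must all be named by species")
  if (!all(sp %in% rownames(X)) || !all(sp %in% rownames(C)))
    stop("species sets of y, X and C differ")
  X <- X[sp, , drop = FALSE]
  C <- C[sp, sp]
  if (max(abs(diag(C) - 1)) > 1e-8) stop("C must have unit diagonal")
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop("C is not positive semi-definite")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  structure(list(y = as.numeric(y), X = X, C = C, species = sp),
            class = "glmm_data")
}

#' Build model data from tree, trait table and environment table
#'
#' Restricts to species present in all three inputs, 2-SD scales the
#' predictors, and computes the phylogenetic correlation matrix.
#'
#' @param tree Ultrametric `phylo`.
#' @param traits Trait table (`species`, `habit`, optional `growth_form`).
#' @param env Species-environment table (`species` + predictor columns).
#' @param predictors Predictor column names.
#' @param growth_form Include scaled growth-form dummy columns.
#' @export
build_glmm_data <- function(tree, traits, env, predictors,
                            growth_form = FALSE) {
  sp <- Reduce(intersect, list(tree$tip.label, traits$species[
    !is.na(traits$habit)], env$species))
  if (length(sp) < 10) stop("fewer than 10 species shared by inputs")
  tr <- prune_tips(tree, setdiff(tree$tip.label, sp))
  C <- phylo_correlation(tr)
  sp <- rownames(C)
  Xraw <- env[match(sp, env$species), predictors, drop = FALSE]
  rownames(Xraw) <- sp
  if (growth_form) {
    gf <- traits$growth_form[match(sp, traits$species)]
    if (is.null(gf)) stop("trait table has no growth_form column")
    lev <- sort(unique(gf))
    for (l in lev[-1]) Xraw[[paste0("growth_form_", l)]] <- as.numeric(gf == l)
  }
  X <- as.matrix(scale_2sd(Xraw))
  rownames(X) <- sp
  y <- setNames(traits$habit[match(sp, traits$species)], sp)
  glmm_data(y, X, C)
}

rinvgamma1 <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)

# one univariate slice-sampling update (Neal 2003, stepping out + shrinkage)
slice1d <- function(x0, logf, w = 1, max_steps = 50) {
  y <- logf(x0) - rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  j <- floor(runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# interweaving (ASIS) re-draw of a random-effect SD: with the Polya-Gamma
# variables fixed the likelihood is Gaussian in sigma given the scaled
# effects re = effect / sigma, and the Huang-Wand prior contributes
# sigma^-(nu+1) exp(-nu / (phi sigma^2)).  Sampled on the log scale.
asis_sigma <- function(sigma, effect, omega, resid_kappa, nu, phi) {
  re <- effect / sigma
  P <- sum(omega * re^2)
  m <- sum(re * resid_kappa)
  logf <- function(t) {
    s <- exp(t)
    -nu * t - nu / (phi * s^2) - 0.5 * P * s^2 + m * s
  }
  exp(slice1d(log(sigma), logf))
}

#' Draw from the posterior by exact Polya-Gamma Gibbs sampling
#'
#' All conditionals are conjugate: Bernoulli observations are augmented with
#' Polya-Gamma latent variables (Devroye sampler), the intercept's Student-t
#' prior and the half-t priors on the random-effect SDs with inverse-gamma
#' auxiliaries (Huang-Wand), so every sweep is an exact Gibbs update.  Runs
#' are bit-reproducible under `seed`.
#'
#' @param data A [glmm_data()].
#' @param spec A [glmm_spec()].
#' @param chains,iter,warmup,thin MCMC settings; the analysis defaults are 4
#'   chains of 10000 iterations (2000 warmup) thinned by 10.
#' @param seed Integer seed.
#' @param sample_prior `"no"` (default) or `"only"` (ignore the data;
#'   returns prior draws, for prior predictive checks).
#' @return An `lh_posterior`: matrices `pars` (b0, beta, sigmas), `a`, `u`
#'   (draws x dimension), `chain` index, per-draw `log_lik` and `log_prior`,
#'   and the inputs.
#' @export
sample_posterior <- function(data, spec, chains = 4, iter = 10000,
                             warmup = 2000, thin = 10, seed = 1,
                             sample_prior = c("no", "only")) {
  sample_prior <- match.arg(sample_prior)
  stopifnot(inherits(data, "glmm_data"), iter > warmup, chains >= 1)
  X <- data$X[, spec$predictors, drop = FALSE]
  y <- data$y
  n <- length(y)
  p <- ncol(X)
  nu <- spec$prior_t_df; ts <- spec$prior_t_scale
  n_keep <- floor((iter - warmup) / thin)
  # jittered Cholesky/inverse of C for the phylogenetic block
  Cj <- data$C + diag(1e-10, n)
  Cinv <- chol2inv(chol(Cj))
  Lc <- t(chol(Cj))
  par_names <- c("b_Intercept", paste0("b_", colnames(X)),
                 "sigma_phylo", "sigma_species")
  run_chain <- function(chain_id) {
    set.seed(seed * 1000L + chain_id)
    if (sample_prior == "only") {
      draws <- matrix(NA_real_, n_keep, p + 3)
      A <- U <- matrix(0, n_keep, n)
      for (d in seq_len(n_keep)) {
        g0 <- rinvgamma1(nu / 2, nu / 2)
        b0 <- rnorm(1, 0, ts * sqrt(g0))
        beta <- rnorm(p, 0, spec$prior_beta_sd)
        sp2 <- rinvgamma1(nu / 2, nu / rinvgamma1(0.5, 1 / ts^2))
        su2 <- rinvgamma1(nu / 2, nu / rinvgamma1(0.5, 1 / ts^2))
        draws[d, ] <- c(b0, beta, sqrt(sp2), sqrt(su2))
        if (spec$include_phylo) A[d, ] <- sqrt(sp2) * (Lc %*% rnorm(n))
        if (spec$include_species_iid) U[d, ] <- rnorm(n, 0, sqrt(su2))
      }
      return(list(draws = draws, a = A, u = U))
    }
    kappa <- y - 0.5
    # initial values
    b0 <- 0; beta <- rep(0, p); a <- rep(0, n); u <- rep(0, n)
    s2p <- 1; s2u <- 1; phi_p <- 1; phi_u <- 1; g0 <- 1
    Xs <- cbind(1, X)
    draws <- matrix(NA_real_, n_keep, p + 3)
    A <- U <- matrix(0, n_keep, n)
    ll <- lp <- numeric(n_keep)
    d <- 0
    for (it in seq_len(iter)) {
      eta <- as.vector(b0 + X %*% beta + a + u)
      omega <- rpg1_cpp(eta)
      # fixed effects block
      P0 <- diag(c(1 / (ts^2 * g0), rep(1 / spec$prior_beta_sd^2, p)),
                 p + 1)
      Pb <- crossprod(Xs * omega, Xs) + P0
      Rb <- chol(Pb)
      mb <- backsolve(Rb, backsolve(Rb, crossprod(Xs, kappa - omega *
                                                    (a + u)),
                                    transpose = TRUE))
      bdraw <- mb + backsolve(Rb, rnorm(p + 1))
      b0 <- bdraw[1]; beta <- bdraw[-1]
      g0 <- rinvgamma1((nu + 1) / 2, (nu + (b0 / ts)^2) / 2)
      fx <- as.vector(X %*% beta) + b0
      if (spec$include_phylo) {
        Pa <- Cinv / s2p
        diag(Pa) <- diag(Pa) + omega
        Ra <- chol(Pa)
        ma <- backsolve(Ra, backsolve(Ra, kappa - omega * (fx + u),
                                      transpose = TRUE))
        a <- as.vector(ma + backsolve(Ra, rnorm(n)))
        qf <- as.numeric(t(a) %*% Cinv %*% a)
        s2p <- rinvgamma1((n + nu) / 2, qf / 2 + nu / phi_p)
        # interweaving step: re-draw sigma in the non-centered form
        sp_new <- asis_sigma(sqrt(s2p), a, omega,
                             kappa - omega * (fx + u), nu, phi_p)
        a <- a * (sp_new / sqrt(s2p))
        s2p <- sp_new^2
        phi_p <- rinvgamma1((nu + 1) / 2, nu / s2p + 1 / ts^2)
      }
      if (spec$include_species_iid) {
        vu <- 1 / (omega + 1 / s2u)
        u <- rnorm(n, vu * (kappa - omega * (fx + a)), sqrt(vu))
        s2u <- rinvgamma1((n + nu) / 2, sum(u^2) / 2 + nu / phi_u)
        su_new <- asis_sigma(sqrt(s2u), u, omega,
                             kappa - omega * (fx + a), nu, phi_u)
        u <- u * (su_new / sqrt(s2u))
        s2u <- su_new^2
        phi_u <- rinvgamma1((nu + 1) / 2, nu / s2u + 1 / ts^2)
      }
      if (it > warmup && (it - warmup) %% thin == 0) {
        d <- d + 1
        draws[d, ] <- c(b0, beta, sqrt(s2p), sqrt(s2u))
        A[d, ] <- a; U[d, ] <- u
        eta <- fx + a + u
        ll[d] <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
        lp[d] <- glmm_log_prior(b0, beta, sqrt(s2p), sqrt(s2u), spec)
      }
    }
    list(draws = draws, a = A, u = U, log_lik = ll, log_prior = lp)
  }
  res <- lapply(seq_len(chains), run_chain)
  pars <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(pars) <- par_names
  out <- list(pars = pars,
              a = do.call(rbind, lapply(res, `[[`, "a")),
              u = do.call(rbind, lapply(res, `[[`, "u")),
              chain = rep(seq_len(chains), each = n_keep),
              log_lik = if (sample_prior == "no")
                unlist(lapply(res, `[[`, "log_lik")) else NULL,
              log_prior = if (sample_prior == "no")
                unlist(lapply(res, `[[`, "log_prior")) else NULL,
              spec = spec, data = data,
              mcmc = list(chains = chains, iter = iter, warmup = warmup,
                          thin = thin, seed = seed))
  class(out) <- "lh_posterior"
  out
}

# log prior density of the top-level parameters (the component power-scaling
# perturbs)
glmm_log_prior <- function(b0, beta, sigma_phylo, sigma_species, spec) {
  ts <- spec$prior_t_scale; nu <- spec$prior_t_df
  lp <- dt(b0 / ts, df = nu, log = TRUE) - log(ts) +
    sum(dnorm(beta, 0, spec$prior_beta_sd, log = TRUE))
  half_t <- function(s) dt(s / ts, df = nu, log = TRUE) - log(ts) + log(2)
  if (spec$include_phylo) lp <- lp + half_t(sigma_phylo)
  if (spec$include_species_iid) lp <- lp + half_t(sigma_species)
  lp
}

#' Convergence and sampling-quality summary
#'
#' Split-Rhat and effective sample size per top-level parameter, plus
#' posterior means, SDs and 95% credible intervals (both mean and median
#' point estimates are reported).
#'
#' @param fit An `lh_posterior`.
#' @export
posterior_summary <- function(fit) {
  ch <- fit$chain
  stats <- t(apply(fit$pars, 2, function(x)
    c(mean = mean(x), median = median(x), sd = sd(x),
      q2.5 = unname(quantile(x, 0.025)),
      q97.5 = unname(quantile(x, 0.975)))))
  rhat <- apply(fit$pars, 2, function(x) split_rhat(x, ch))
  ess <- apply(fit$pars, 2, function(x) ess_mean(x, ch))
  data.frame(parameter = colnames(fit$pars), stats, rhat = rhat, ess = ess,
             row.names = NULL)
}

#' Split-Rhat convergence diagnostic
#' @param x Draw vector.
#' @param chain Chain index per draw.
#' @export
split_rhat <- function(x, chain) {
  xs <- split(x, chain)
  halves <- unlist(lapply(xs, function(v) {
    m <- floor(length(v) / 2)
    list(v[seq_len(m)], v[(length(v) - m + 1):length(v)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (chain-averaged autocorrelation, Geyer truncation)
#' @inheritParams split_rhat
#' @export
ess_mean <- function(x, chain) {
  xs <- split(x, chain)
  n <- min(lengths(xs)); m <- length(xs)
  if (n < 4) return(m * n)
  W <- mean(vapply(xs, var, numeric(1)))
  vplus <- (n - 1) / n * W + var(vapply(xs, mean, numeric(1)))
  if (vplus == 0) return(m * n)
  max_lag <- min(n - 2, 200)
  rho <- numeric(max_lag)
  for (l in seq_len(max_lag)) {
    acov <- mean(vapply(xs, function(v) {
      mean((v[1:(n - l)] - mean(v)) * (v[(1 + l):n] - mean(v)))
    }, numeric(1)))
    rho[l] <- 1 - (W - acov) / vplus
  }
  # Geyer initial positive sequence on paired sums
  s <- 0; l <- 1
  prev_pair <- Inf
  while (l + 1 <= max_lag) {
    pair <- rho[l] + rho[l + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)  # initial monotone
    s <- s + pair
    prev_pair <- pair
    l <- l + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Bayesian R-squared for the Bernoulli multilevel model
#'
#' Per posterior draw, fitted probabilities are formed on the probability
#' scale and `R2 = var(p) / (var(p) + mean(p (1 - p)))`; `marginal` sets the
#' random effects to zero (variance explained by environmental predictors
#' alone), `conditional` includes them.
#'
#' @param fit An `lh_posterior`.
#' @param mode `"marginal"` or `"conditional"`.
#' @param scale `"probability"` (default) or `"logit"` (latent scale with
#'   residual variance pi^2 / 3).
#' @return List with `mean`, `ci` (95%), and the per-draw values.
#' @export
bayes_r2 <- function(fit, mode = c("marginal", "conditional"),
                     scale = c("probability", "logit")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  X <- fit$data$X[, fit$spec$predictors, drop = FALSE]
  p <- ncol(X)
  draws <- vapply(seq_len(nrow(fit$pars)), function(d) {
    eta <- fit$pars[d, 1] + as.vector(X %*% fit$pars[d, 2:(p + 1)])
    if (mode == "conditional") eta <- eta + fit$a[d, ] + fit$u[d, ]
    if (scale == "logit") {
      vf <- var(eta)
      return(vf / (vf + pi^2 / 3))
    }
    pr <- plogis(eta)
    vf <- var(pr)
    if (vf == 0) return(0)
    vf / (vf + mean(pr * (1 - pr)))
  }, numeric(1))
  list(mean = mean(draws), ci = unname(quantile(draws, c(0.025, 0.975))),
       draws = draws)
}

#' Posterior predictive check
#'
#' Replicates the response under each posterior draw (conditional fitted
#' probabilities) and reports where the observed statistic falls within the
#' replicated distribution.
#'
#' @param fit An `lh_posterior` (at least 100 draws).
#' @param stat Function of the binary response vector (default `mean`).
#' @param seed Seed for the replicate draws.
#' @return List with `observed`, `quantile` of the observed value among
#'   replicates, and the replicate statistics.
#' @export
posterior_predictive_check <- function(fit, stat = mean, seed = 1) {
  if (nrow(fit$pars) < 100) stop("need at least 100 posterior draws")
  X <- fit$data$X[, fit$spec$predictors, drop = FALSE]
  p <- ncol(X)
  y <- fit$data$y
  set.seed(seed)
  reps <- vapply(seq_len(nrow(fit$pars)), function(d) {
    eta <- fit$pars[d, 1] + as.vector(X %*% fit$pars[d, 2:(p + 1)]) +
      fit$a[d, ] + fit$u[d, ]
    stat(rbinom(length(y), 1, plogis(eta)))
  }, numeric(1))
  obs <- stat(y)
  list(observed = obs, quantile = mean(reps < obs) + 0.5 * mean(reps == obs),
       replicates = reps)
}

# symmetrized cumulative Jensen-Shannon distance between the base posterior
# and an importance-weighted one, on a shared support (scale-normalized)
cjs_dist <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  n <- length(x)
  if (x[n] == x[1]) return(0)
  P <- (seq_len(n)) / n          # base ECDF (uniform weights)
  Q <- cumsum(w)
  dx <- diff(x)
  P <- P[-n]; Q <- Q[-n]
  cjs_pq <- sum(P * log2(2 * P / (P + Q)) * dx, na.rm = TRUE) +
    sum((Q - P) * dx) / (2 * log(2))
  cjs_qp <- sum(Q * log2(2 * Q / (P + Q)) * dx, na.rm = TRUE) +
    sum((P - Q) * dx) / (2 * log(2))
  bound <- sum(((P + Q) / 2) * dx) / log(2) + sum(abs(Q - P) * dx)
  if (bound <= 0) return(0)
  sqrt(max(0.5 * (cjs_pq + cjs_qp), 0) / bound)
}

#' Prior/likelihood power-scaling sensitivity
#'
#' Reweights the stored posterior draws as if the prior (or likelihood) had
#' been raised to a power alpha, using the per-draw log prior/likelihood:
#' weights proportional to `exp((alpha - 1) * log_component)`.  Reports the
#' drift of the posterior mean and quantiles and a distributional distance
#' per parameter, plus the effective sample size of the weights.
#'
#' @param fit An `lh_posterior` with stored `log_prior` / `log_lik`.
#' @param alphas Scaling powers (default 0.5 and 2).
#' @param component `"prior"` (default) or `"likelihood"`.
#' @param threshold Distance above which a parameter is flagged sensitive
#'   (default 0.05).
#' @return data.frame with one row per parameter x alpha.
#' @export
power_scale_sensitivity <- function(fit, alphas = c(0.5, 2),
                                    component = c("prior", "likelihood"),
                                    threshold = 0.05) {
  component <- match.arg(component)
  lcomp <- if (component == "prior") fit$log_prior else fit$log_lik
  if (is.null(lcomp)) stop("fit carries no per-draw log ", component)
  out <- list()
  for (al in alphas) {
    lw <- (al - 1) * lcomp
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    ess_w <- 1 / sum(w^2)
    if (ess_w < 0.1 * length(w))
      warning("weight ESS below 10% of draws at alpha = ", al,
              "; sensitivity estimates unreliable", call. = FALSE)
    for (j in seq_len(ncol(fit$pars))) {
      x <- fit$pars[, j]
      dist <- cjs_dist(x, w)
      out[[length(out) + 1]] <- data.frame(
        parameter = colnames(fit$pars)[j], alpha = al,
        mean_base = mean(x), mean_scaled = sum(w * x),
        drift = sum(w * x) - mean(x), distance = dist,
        weight_ess = ess_w, flagged = dist > threshold)
    }
  }
  do.call(rbind, out)
}

#' Compare model variants by Bayesian R-squared
#'
#' Refits the model for each predictor-set variant (sharing response and
#' phylogenetic structure) and tabulates marginal and conditional Bayesian
#' R-squared.
#'
#' @param data A [glmm_data()] containing every predictor any variant uses.
#' @param variants Named list of predictor-name vectors (e.g. full,
#'   minus-AI, minus-GSP, plus-growth-form).
#' @param ... Passed to [sample_posterior()] (chains, iter, seed, ...).
#' @return List with `table` (R2 means and CIs per variant) and `fits`.
#' @export
compare_model_variants <- function(data, variants, ...) {
  fits <- lapply(variants, function(pred) {
    sample_posterior(data, glmm_spec(pred), ...)
  })
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    rm <- bayes_r2(fits[[nm]], "marginal")
    rc <- bayes_r2(fits[[nm]], "conditional")
    data.frame(variant = nm,
               r2_marginal = rm$mean, r2_marginal_lo = rm$ci[1],
               r2_marginal_hi = rm$ci[2],
               r2_conditional = rc$mean, r2_conditional_lo = rc$ci[1],
               r2_conditional_hi = rc$ci[2])
  }))
  list(table = tab, fits = fits)
}
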