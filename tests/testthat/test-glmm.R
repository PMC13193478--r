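small_glmm_setup <- function(n = 40, seed = 81, beta = c(1.2, -0.8),
                             sigma_phylo = 0.8, sigma_species = 0.5) {
  tr <- sim_tree(n, height = 1, seed = seed)
  sim <- simulate_glmm_dataset(tr, b0 = -0.5, beta = beta,
                               sigma_phylo = sigma_phylo,
                               sigma_species = sigma_species,
                               seed = seed + 1)
  list(tree = tr, sim = sim,
       data = glmm_data(sim$y, sim$X, sim$C),
       spec = glmm_spec(colnames(sim$X)))
}

test_that("glmm_data validates alignment and matrix structure", {
  s <- small_glmm_setup()
  expect_s3_class(s$data, "glmm_data")
  badC <- s$sim$C
  diag(badC) <- 2
  expect_error(glmm_data(s$sim$y, s$sim$X, badC), "unit diagonal")
  y2 <- s$sim$y
  y2[1] <- 3
  expect_error(glmm_data(y2, s$sim$X, s$sim$C), "binary")
  expect_error(glmm_data(unname(s$sim$y), s$sim$X, s$sim$C), "named")
})

test_that("the sampler is seed-reproducible and passes basic diagnostics", {
  s <- small_glmm_setup()
  f1 <- sample_posterior(s$data, s$spec, chains = 2, iter = 800,
                         warmup = 200, thin = 2, seed = 5)
  f2 <- sample_posterior(s$data, s$spec, chains = 2, iter = 800,
                         warmup = 200, thin = 2, seed = 5)
  expect_identical(f1$pars, f2$pars)
  expect_identical(f1$a, f2$a)
  sm <- posterior_summary(f1)
  expect_true(all(is.finite(sm$mean)))
  expect_true(all(sm$rhat < 1.2))
  expect_true(all(f1$pars[, "sigma_phylo"] > 0))
})

test_that("prior-only sampling recovers the stated priors", {
  s <- small_glmm_setup()
  pf <- sample_posterior(s$data, s$spec, chains = 2, iter = 12500,
                         warmup = 500, thin = 1, seed = 3,
                         sample_prior = "only")
  sds <- apply(pf$pars[, c("b_x1", "b_x2")], 2, sd)
  expect_true(all(abs(sds - 2) / 2 < 0.05))
  # intercept prior: Student-t(3, 0, 2.5) quartiles
  expect_equal(unname(quantile(pf$pars[, "b_Intercept"], 0.75)),
               2.5 * qt(0.75, df = 3), tolerance = 0.1)
})

test_that("posteriors match an independent MCMC implementation (JAGS)", {
  skip_if_not_installed("rjags")
  s <- small_glmm_setup(n = 30, seed = 91)
  fit <- sample_posterior(s$data, s$spec, chains = 2, iter = 10000,
                          warmup = 1000, thin = 2, seed = 11)
  n <- length(s$data$y)
  L <- t(chol(s$data$C + diag(1e-10, n)))
  model_str <- "
    model {
      for (i in 1:n) {
        y[i] ~ dbern(prob[i])
        logit(prob[i]) <- b0 + inprod(X[i,], beta) + a[i] + u[i]
        u[i] ~ dnorm(0, tau_u)
        z[i] ~ dnorm(0, 1)
      }
      a[1:n] <- sig_a * (L[1:n, 1:n] %*% z[1:n])
      b0 ~ dt(0, pow(2.5, -2), 3)
      for (k in 1:np) { beta[k] ~ dnorm(0, 0.25) }
      sig_a ~ dt(0, pow(2.5, -2), 3) T(0,)
      sig_u ~ dt(0, pow(2.5, -2), 3) T(0,)
      tau_u <- pow(sig_u, -2)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = s$data$y, X = s$data$X, L = L, n = n,
                np = ncol(s$data$X)),
    inits = lapply(7:8, function(sd)
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = sd,
           sig_a = 1, sig_u = 1, b0 = 0,
           beta = rep(0, ncol(s$data$X)))),
    n.chains = 2, n.adapt = 1000, quiet = TRUE)
  sm <- rjags::coda.samples(jm, c("b0", "beta", "sig_a", "sig_u"), 50000,
                            thin = 5)
  jdraw <- do.call(rbind, lapply(sm, as.matrix))
  ours <- colMeans(fit$pars)
  theirs <- c(jdraw[, "b0"] |> mean(), mean(jdraw[, "beta[1]"]),
              mean(jdraw[, "beta[2]"]), mean(jdraw[, "sig_a"]),
              mean(jdraw[, "sig_u"]))
  expect_lt(max(abs(unname(ours) - theirs)), 0.4)
})

test_that("Bayesian R2 is 0 for a flat model and conditional >= marginal", {
  s <- small_glmm_setup()
  fit <- sample_posterior(s$data, s$spec, chains = 2, iter = 800,
                          warmup = 200, thin = 2, seed = 6)
  # degenerate draws: beta = 0, no random effects
  flat <- fit
  flat$pars[] <- 0
  flat$a[] <- 0
  flat$u[] <- 0
  expect_equal(bayes_r2(flat, "marginal")$mean, 0)
  expect_equal(bayes_r2(flat, "conditional")$mean, 0)
  expect_gte(bayes_r2(fit, "conditional")$mean,
             bayes_r2(fit, "marginal")$mean)
  # strong fixed effects, no random effects: marginal ~ conditional
  tr <- sim_tree(120, height = 1, seed = 93)
  sim <- simulate_glmm_dataset(tr, 0, c(4, -4), 0, 0, seed = 94)
  d2 <- glmm_data(sim$y, sim$X, sim$C)
  f2 <- sample_posterior(d2, glmm_spec(colnames(sim$X)), chains = 2,
                         iter = 1500, warmup = 500, thin = 2, seed = 7)
  expect_lt(abs(bayes_r2(f2, "conditional")$mean -
                  bayes_r2(f2, "marginal")$mean), 0.12)
})

test_that("posterior predictive checks calibrate and catch misfit", {
  s <- small_glmm_setup(n = 60, seed = 95)
  fit <- sample_posterior(s$data, s$spec, chains = 2, iter = 1200,
                          warmup = 200, thin = 2, seed = 8)
  ppc <- posterior_predictive_check(fit, seed = 1)
  expect_gt(ppc$quantile, 0.05)
  expect_lt(ppc$quantile, 0.95)
  # an intercept-only model forced onto strongly structured data misses the
  # predictor-sorted top-half mean
  tr <- sim_tree(150, height = 1, seed = 96)
  sim <- simulate_glmm_dataset(tr, 0, c(5), 0, 0, seed = 97)
  d2 <- glmm_data(sim$y, sim$X, sim$C)
  f0 <- sample_posterior(d2, glmm_spec("x1"), chains = 1, iter = 700,
                         warmup = 200, thin = 1, seed = 9)
  f0$pars[, "b_x1"] <- 0  # beta forced to zero
  top <- order(sim$X[, 1], decreasing = TRUE)[1:50]
  stat <- function(y) mean(y[top])
  ppc0 <- posterior_predictive_check(f0, stat = stat, seed = 2)
  expect_true(ppc0$quantile < 0.05 || ppc0$quantile > 0.95)
})

test_that("power-scaling is the identity at alpha 1 and fades with data", {
  s <- small_glmm_setup()
  fit <- sample_posterior(s$data, s$spec, chains = 2, iter = 1200,
                          warmup = 200, thin = 2, seed = 10)
  id <- power_scale_sensitivity(fit, alphas = 1)
  expect_equal(max(abs(id$drift)), 0, tolerance = 1e-12)
  expect_lt(max(id$distance), 1e-6)
  ps <- suppressWarnings(power_scale_sensitivity(fit, alphas = c(0.5, 2)))
  expect_true(all(is.finite(ps$distance)))
  expect_true(all(ps$weight_ess > 0))
})

test_that("variant comparison reports R2 per predictor set", {
  s <- small_glmm_setup(n = 50, seed = 98)
  cmp <- compare_model_variants(
    s$data, list(full = c("x1", "x2"), minus_x2 = "x1"),
    chains = 1, iter = 600, warmup = 200, thin = 2, seed = 12)
  expect_equal(cmp$table$variant, c("full", "minus_x2"))
  expect_true(all(cmp$table$r2_conditional >= cmp$table$r2_marginal - 1e-9))
})
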