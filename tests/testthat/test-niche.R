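single_regime_map <- function(tree, regime = "0") {
  structure(list(tree = tree,
                 maps = lapply(tree$edge.length, function(l)
                   setNames(l, regime)),
                 node_states = rep(as.integer(regime),
                                   ape::Ntip(tree) + tree$Nnode)),
            class = "regime_map")
}

test_that("model names map bijectively to vary flags and parameter counts", {
  ks <- vapply(ou_model_names(), function(n) ou_model_spec(n)$k, numeric(1))
  expect_equal(unname(ks), c(2, 3, 3, 4, 4, 4, 5, 5, 6))
  ouv <- ou_model_spec("OUV")
  expect_true(ouv$vary_sigma)
  expect_false(ouv$vary_alpha)
  expect_false(ouv$vary_theta)
  expect_false(ou_model_spec("BMV")$is_ou)
})

test_that("OU tip moments recover the BM limit and the stationary variance", {
  tr <- sim_tree(8, height = 2, seed = 51)
  mp <- single_regime_map(tr)
  mo <- ou_tip_moments(tr, mp, ou_model_spec("OU1"),
                       c(sigma2 = 2, alpha = 1e-10, theta = .3))
  bm <- 2 * ape::vcv.phylo(tr)
  expect_lt(max(abs(mo$cov - bm[rownames(mo$cov), colnames(mo$cov)])) /
              max(bm), 1e-6)
  moS <- ou_tip_moments(tr, mp, ou_model_spec("OU1"),
                        c(sigma2 = 2, alpha = 40, theta = .3))
  expect_lt(max(abs(diag(moS$cov) - 2 / (2 * 40))) / (2 / 80), 1e-6)
  expect_equal(unname(moS$mean), rep(.3, 8), tolerance = 1e-8)
})

test_that("two-regime moments match exact-transition simulation moments", {
  tr <- sim_tree(3, height = 2, seed = 52)
  set.seed(53)
  st <- setNames(c(0L, 1L, 1L), tr$tip.label)
  mp <- stochastic_maps(tr, st, .6, .4, n_maps = 1, seed = 7)[[1]]
  spec <- ou_model_spec("OUMVA")
  par <- c(sigma2_0 = 1, sigma2_1 = 3, alpha_0 = .5, alpha_1 = .9,
           theta_0 = 0, theta_1 = 2)
  mo <- ou_tip_moments(tr, mp, spec, par)
  rr <- mp$node_states[4]
  sims <- vapply(seq_len(20000), function(i)
    simulate_ou_traits(tr, mp, c(1, 3), c(.5, .9), c(0, 2),
                       root_value = c(0, 2)[rr + 1], seed = i),
    numeric(3))
  expect_lt(max(abs(rowMeans(sims) - mo$mean)), 0.03)
  expect_lt(max(abs(cov(t(sims)) - mo$cov)), 0.04)
  # PSD on random paintings
  ev <- eigen(mo$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("niche log-likelihood equals the closed-form Gaussian density", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  mp <- single_regime_map(tr)
  x <- setNames(c(.4, -.3), c("A", "B"))
  par <- c(sigma2 = 1.5, alpha = .7, theta = .2)
  v <- 1.5 * (1 - exp(-2 * .7)) / 1.4
  expect_equal(niche_loglik(tr, mp, x, ou_model_spec("OU1"), par),
               sum(dnorm(c(.4, -.3), .2, sqrt(v), log = TRUE)))
  # 3-tip closed form with shared ancestry under BM
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  mp3 <- single_regime_map(tr3)
  x3 <- setNames(c(.1, -.2, .5), c("A", "B", "C"))
  S <- 2 * ape::vcv.phylo(tr3)[c("A", "B", "C"), c("A", "B", "C")]
  ch <- chol(S)
  z <- backsolve(ch, x3 - 1, transpose = TRUE)
  ld <- -0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  expect_equal(niche_loglik(tr3, mp3, x3, ou_model_spec("BM1"),
                            c(sigma2 = 2, z0 = 1)), ld)
})

test_that("BM1 ignores the painting; duplicate maps collapse; weights sum to 1", {
  tr <- sim_tree(10, height = 3, seed = 54)
  set.seed(55)
  st <- setNames(sample(0:1, 10, replace = TRUE), tr$tip.label)
  maps <- stochastic_maps(tr, st, .5, .5, n_maps = 3, seed = 8)
  x <- setNames(rnorm(10), tr$tip.label)
  bm <- ou_model_spec("BM1")
  par <- c(sigma2 = 1.2, z0 = 0)
  lls <- vapply(maps, function(m) niche_loglik(tr, m, x, bm, par),
                numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-12)
  ou1 <- ou_model_spec("OU1")
  p1 <- c(sigma2 = 1, alpha = .4, theta = 0)
  expect_equal(niche_loglik(tr, maps[c(1, 1, 1)], x, ou1, p1),
               niche_loglik(tr, maps[1], x, ou1, p1))
})

test_that("constraining a richer model reproduces the nested model exactly", {
  tr <- sim_tree(12, height = 3, seed = 56)
  set.seed(57)
  st <- setNames(sample(0:1, 12, replace = TRUE), tr$tip.label)
  mp <- stochastic_maps(tr, st, .5, .4, n_maps = 2, seed = 9)
  x <- setNames(rnorm(12), tr$tip.label)
  ll_ou1 <- niche_loglik(tr, mp, x, ou_model_spec("OU1"),
                         c(sigma2 = 1.3, alpha = .6, theta = .2))
  ll_oumva <- niche_loglik(tr, mp, x, ou_model_spec("OUMVA"),
                           c(sigma2_0 = 1.3, sigma2_1 = 1.3, alpha_0 = .6,
                             alpha_1 = .6, theta_0 = .2, theta_1 = .2))
  expect_equal(ll_oumva, ll_ou1, tolerance = 1e-12)
  ll_bm1 <- niche_loglik(tr, mp, x, ou_model_spec("BM1"),
                         c(sigma2 = .9, z0 = .1))
  ll_bmv <- niche_loglik(tr, mp, x, ou_model_spec("BMV"),
                         c(sigma2_0 = .9, sigma2_1 = .9, z0 = .1))
  expect_equal(ll_bmv, ll_bm1, tolerance = 1e-12)
})

test_that("trait rescaling shifts sigma2/theta but leaves AICc contrasts alone", {
  tr <- sim_tree(40, height = 3, seed = 58)
  set.seed(59)
  st <- setNames(sample(0:1, 40, replace = TRUE), tr$tip.label)
  maps <- stochastic_maps(tr, st, .5, .4, n_maps = 2, seed = 10)
  x <- simulate_ou_traits(tr, maps[[1]], c(1, 3), c(.8, .8), c(0, 0),
                          root_value = 0, seed = 3)
  cc <- 10
  f1 <- fit_niche_model(tr, maps, x, ou_model_spec("OUV"), n_starts = 2,
                        seed = 1)
  f2 <- fit_niche_model(tr, maps, x * cc, ou_model_spec("OUV"),
                        n_starts = 2, seed = 1)
  expect_equal(f2$par[["sigma2_0"]] / f1$par[["sigma2_0"]], cc^2,
               tolerance = 0.05)
  expect_equal(f2$par[["alpha"]], f1$par[["alpha"]], tolerance = 0.05)
  g1 <- fit_niche_model(tr, maps, x, ou_model_spec("OU1"), n_starts = 2,
                        seed = 1)
  g2 <- fit_niche_model(tr, maps, x * cc, ou_model_spec("OU1"),
                        n_starts = 2, seed = 1)
  expect_equal(f2$AICc - g2$AICc, f1$AICc - g1$AICc, tolerance = 0.05)
})

test_that("the nine-model table ranks by AICc with unit-sum weights", {
  tr <- sim_tree(30, height = 3, seed = 60)
  set.seed(61)
  st <- setNames(sample(0:1, 30, replace = TRUE), tr$tip.label)
  maps <- stochastic_maps(tr, st, .5, .4, n_maps = 2, seed = 11)
  x <- setNames(rnorm(30), tr$tip.label)
  res <- fit_niche_models(tr, maps, x, n_starts = 1, seed = 2)
  expect_equal(nrow(res$table), 9)
  expect_equal(sum(res$table$AICw), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(res$table$AICc))
  # AICc definition
  f <- res$fits$OU1
  expect_equal(f$AICc, 2 * f$k - 2 * f$loglik +
                 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
})
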