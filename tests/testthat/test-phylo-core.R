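test_that("read_newick parses, reports height and flags non-ultrametric trees", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- read_newick(tf)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(attr(tr, "root_age"), 2)
  expect_true(attr(tr, "ultrametric"))

  writeLines("((A:1,B:2):1,C:2);", tf)
  expect_warning(tr2 <- read_newick(tf), "not ultrametric")
  expect_false(attr(tr2, "ultrametric"))

  writeLines("((A:1,B:1:1,C:2);", tf)
  expect_error(read_newick(tf))
  writeLines("((A,B),C);", tf)
  expect_error(read_newick(tf), "branch length")
})

test_that("normalize_depths repairs rounding noise only", {
  tr <- sim_tree(10, height = 5)
  noisy <- tr
  term <- match(seq_len(10), noisy$edge[, 2])
  set.seed(1)
  noisy$edge.length[term] <- noisy$edge.length[term] + runif(10, 0, 1e-5)
  fixed <- suppressWarnings(normalize_depths(noisy))
  expect_true(attr(fixed, "ultrametric"))
  bad <- tr
  bad$edge.length[term[1]] <- bad$edge.length[term[1]] + 2
  expect_error(suppressWarnings(normalize_depths(bad)), "spread")
})

test_that("prune_tips preserves patristic distances among retained tips", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pr <- prune_tips(tr, "C")
  expect_equal(sort(pr$tip.label), c("A", "B"))
  expect_equal(unname(ape::cophenetic.phylo(pr)["A", "B"]), 2)
  expect_identical(prune_tips(tr, character(0)), tr)

  big <- sim_tree(50, height = 8, seed = 3)
  set.seed(4)
  drop <- sample(big$tip.label, 10)
  kept <- setdiff(big$tip.label, drop)
  d0 <- ape::cophenetic.phylo(big)[kept, kept]
  d1 <- ape::cophenetic.phylo(prune_tips(big, drop))[kept, kept]
  expect_equal(d1, d0, tolerance = 1e-12)
  expect_error(prune_tips(tr, tr$tip.label), "all tips")
  expect_error(prune_tips(tr, "ZZZ"), "not in tree")
})

test_that("phylo_correlation gives shared-depth correlations, PSD, unit diagonal", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_correlation(star)), diag(4))
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_correlation(tr)
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  for (s in 1:5) {
    Ci <- phylo_correlation(sim_tree(15, height = 3, seed = s))
    expect_equal(unname(diag(Ci)), rep(1, 15))
    expect_gte(min(eigen(Ci, symmetric = TRUE)$values), -1e-10)
  }
  nu <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(suppressWarnings(phylo_correlation(nu)), "ultrametric")
})

test_that("phylo_correlation matches Brownian simulation covariance", {
  tr <- sim_tree(20, height = 1, seed = 9)
  C <- phylo_correlation(tr)
  set.seed(10)
  X <- t(replicate(30000, {
    x <- numeric(20 + tr$Nnode)
    pt <- ape::reorder.phylo(tr, "postorder")
    for (e in rev(seq_len(nrow(pt$edge))))
      x[pt$edge[e, 2]] <- x[pt$edge[e, 1]] +
        rnorm(1, 0, sqrt(pt$edge.length[e]))
    x[seq_len(20)]
  }))
  colnames(X) <- tr$tip.label
  expect_lt(max(abs(cov(X)[rownames(C), colnames(C)] - C)), 0.03)
})

test_that("trait tables decode habit strings and catch duplicates", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,habit", "a,deciduous", "b,evergreen", "c,1",
               "d,"), tf)
  tt <- read_trait_table(tf)
  expect_equal(tt$habit, c(1L, 0L, 1L, NA))
  writeLines(c("species,habit", "a,deciduous", "a,evergreen"), tf)
  expect_error(read_trait_table(tf), "duplicated")
})

test_that("mk_loglik: trivial case and enumeration oracle on small trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  st <- setNames(c(0L, 0L, 0L), c("A", "B", "C"))
  expect_equal(mk_loglik(tr, st, 0, 0), log(0.5))
  for (s in 1:4) {
    n <- sample(4:6, 1)
    tri <- sim_tree(n, height = 2, seed = 100 + s)
    set.seed(200 + s)
    sti <- setNames(sample(0:1, n, replace = TRUE), tri$tip.label)
    q <- runif(2, 0.05, 0.8)
    expect_equal(mk_loglik(tri, sti, q[1], q[2]),
                 enum_mk_loglik(tri, sti, q[1], q[2]), tolerance = 1e-8)
  }
  expect_error(mk_loglik(tr, st, -1, 0.1), "non-negative")
  expect_error(mk_loglik(tr, setNames(c(0L, 2L, 0L), names(st)), .1, .1))
})

test_that("mk_loglik agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- sim_tree(25, height = 4, seed = 5)
  set.seed(6)
  st <- setNames(sample(0:1, 25, replace = TRUE), tr$tip.label)
  ref <- phytools::fitMk(tr, setNames(factor(st), names(st)),
                         fixedQ = matrix(c(-0.3, 0.3, 0.1, -0.1), 2, 2,
                                         byrow = TRUE), pi = c(0.5, 0.5))
  expect_equal(mk_loglik(tr, st, 0.3, 0.1), ref$logLik, tolerance = 1e-6)
})

sim_mk_states <- function(tree, q01, q10, root_state = 0L, seed = 1) {
  set.seed(seed)
  n_node <- ape::Ntip(tree) + tree$Nnode
  st <- integer(n_node)
  st[ape::Ntip(tree) + 1L] <- root_state
  pt <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(pt$edge)))) {
    P <- mk_prob(pt$edge.length[e], q01, q10)
    st[pt$edge[e, 2]] <- sample(0:1, 1, prob = P[st[pt$edge[e, 1]] + 1, ])
  }
  setNames(st[seq_len(ape::Ntip(tree))], tree$tip.label)
}

test_that("fit_mk_ard recovers rates, respects time rescaling, flags boundaries", {
  tr <- sim_tree(30, height = 6, seed = 7)
  st <- sim_mk_states(tr, 0.25, 0.12, seed = 8)
  f1 <- fit_mk_ard(tr, st, n_starts = 3, seed = 1)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  f2 <- fit_mk_ard(tr2, st, n_starts = 3, seed = 1)
  expect_equal(f2$q01, f1$q01 / 2, tolerance = 1e-3)
  expect_equal(f2$q10, f1$q10 / 2, tolerance = 1e-3)
  all1 <- setNames(rep(1L, 30), tr$tip.label)
  expect_warning(fb <- fit_mk_ard(tr, all1, n_starts = 2, seed = 1),
                 "boundary")
  expect_lt(fb$q10, 1e-6)
})

test_that("stochastic maps are consistent with tips and converge to marginals", {
  tr <- sim_tree(5, height = 3, seed = 11)
  set.seed(12)
  st <- setNames(sample(0:1, 5, replace = TRUE), tr$tip.label)
  # q -> 0, uniform tip state: every map single-regime
  all0 <- setNames(rep(0L, 5), tr$tip.label)
  m0 <- stochastic_maps(tr, all0, 1e-9, 1e-9, n_maps = 5, seed = 1)
  for (m in m0) {
    expect_true(all(m$node_states == 0))
    expect_true(all(vapply(m$maps, length, integer(1)) == 1))
  }
  # segment durations always sum to branch lengths
  maps <- stochastic_maps(tr, st, 0.4, 0.25, n_maps = 3000, seed = 2)
  expect_true(all(abs(vapply(maps[[1]]$maps, sum, numeric(1)) -
                        tr$edge.length) < 1e-12))
  # node frequencies match pruning-based marginal posteriors
  mg <- mk_marginal_states(tr, st, 0.4, 0.25)
  freq <- rowMeans(vapply(maps, function(m) m$node_states, integer(9)) == 1)
  for (v in 6:9)
    expect_lt(abs(freq[v] - mg[v, 2]),
              3 * sqrt(mg[v, 2] * (1 - mg[v, 2]) / 3000) + 1e-3)
  # expected transitions grow with the rates
  mean_trans <- vapply(c(0.01, 0.1, 1), function(q) {
    mean(vapply(stochastic_maps(tr, st, q, q, n_maps = 150, seed = 3),
                count_transitions, integer(1)))
  }, numeric(1))
  expect_true(all(diff(mean_trans) > 0))
})

test_that("stochastic map node frequencies also match an external mapper", {
  skip_if_not_installed("phytools")
  tr <- sim_tree(6, height = 3, seed = 13)
  set.seed(14)
  st <- setNames(sample(0:1, 6, replace = TRUE), tr$tip.label)
  Q <- matrix(c(-0.3, 0.3, 0.2, -0.2), 2, 2, byrow = TRUE,
              dimnames = list(0:1, 0:1))
  ours <- stochastic_maps(tr, st, 0.3, 0.2, n_maps = 1500, seed = 4)
  ref <- phytools::make.simmap(tr, setNames(factor(st), names(st)), Q = Q,
                               pi = c(0.5, 0.5), nsim = 1500,
                               message = FALSE)
  f_ours <- rowMeans(vapply(ours, function(m) m$node_states,
                            integer(11)) == 1)[7:11]
  f_ref <- vapply(7:11, function(v)
    mean(vapply(ref, function(m) {
      e <- which(m$edge[, 1] == v)[1]
      names(m$maps[[e]])[1] == "1"
    }, logical(1))), numeric(1))
  expect_lt(max(abs(f_ours - f_ref)), 0.05)
})

test_that("species matching normalizes separators and reports mismatches", {
  tr <- ape::read.tree(text = "((Genus_a:1,Genus_b:1):1,Genus_c:2);")
  expect_message(m <- match_species(tr, c("Genus a", "Genus b", "Genus x")),
                 "not found")
  expect_equal(m$tree_index[1:2], c(1L, 2L))
  expect_true(is.na(m$tree_index[3]))
  expect_equal(m$unmatched_tips, "Genus_c")
})
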