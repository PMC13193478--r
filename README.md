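# leafhabit

Eco-evolutionary analysis of dry-season deciduousness on time-calibrated
phylogenies.

Tropical woody clades mix two drought strategies: *deciduous* species shed
all leaves in the dry season, *evergreen* species keep transpiring and
resist embolism instead.  `leafhabit` implements the comparative toolkit
needed to ask, for a clade scored for this binary leaf habit, three linked
questions:

1. **Did leaf habit shape diversification, and did that change through
   time?**  Maximum-likelihood state-dependent speciation–extinction (SSE)
   models with two observed × two hidden states, time-stratified at an
   epoch boundary (e.g. 7 or 15 Ma): per composite state *s*, speciation
   λ\_s and extinction μ\_s enter the standard backward equations

   dE\_s/dt = μ\_s − (λ\_s+μ\_s+Σq\_sj)E\_s + λ\_s E\_s² + Σ\_j q\_sj E\_j,
   dD\_s/dt = −(λ\_s+μ\_s+Σq\_sj)D\_s + 2λ\_s E\_s D\_s + Σ\_j q\_sj D\_j,

   with all rates free to switch at the slice age.  An 18-model family
   crosses trait-dependent vs hidden-state ("character-independent")
   speciation in each epoch, symmetric vs asymmetric and constant vs
   epoch-varying transitions, ranked by AIC.
2. **Does leaf habit structure environmental-niche evolution?**  Nine
   BM/OU models (BM1, BMV, OU1, OUA, OUV, OUM, OUVA, OUMV, OUMVA) letting
   σ², α and θ differ between deciduous and evergreen selective regimes,
   evaluated over stochastic character maps drawn under a fitted ARD Mk
   model and ranked by AICc / Akaike weights, per environmental variable
   (aridity index, vapor pressure deficit, growing-season precipitation,
   soil clay and sand fractions).
3. **What predicts deciduousness across species today?**  A Bayesian
   phylogenetic multilevel Bernoulli regression,
   logit P(y=1) = β₀ + Xβ + a + u with a ~ MVN(0, σ²\_phylo C) and
   u ~ N(0, σ²\_species), fitted by an exact Pólya–Gamma Gibbs sampler,
   with marginal/conditional Bayesian R², posterior predictive checks and
   prior power-scaling sensitivity.

Around these sit the data-preparation stage (native-range filtering,
convex hulls, random points for data-poor species, 1.5-km spatial
thinning, VIF screening, 2-SD predictor scaling), seeded synthetic-data
generators for every stage, and a pipeline orchestrator
(`run_pipeline()`, with a thin CLI at `inst/cli/leafhabit-pipeline.R`).

## Worked example

Simulate a 150-species clade whose deciduousness follows one environmental
predictor plus phylogenetically correlated and independent species
effects, then refit the generating model:

```r
library(leafhabit)
set.seed(1)
tree <- ape::rcoal(150)
tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
sim <- simulate_glmm_dataset(tree, b0 = -1, beta = c(1.5, -1),
                             sigma_phylo = 1, sigma_species = 0.5, seed = 4)
dat <- glmm_data(sim$y, sim$X, sim$C)
fit <- sample_posterior(dat, glmm_spec(c("x1", "x2")),
                        chains = 4, iter = 4000, warmup = 1000, thin = 4,
                        seed = 9)
posterior_summary(fit)[, c("parameter", "mean", "q2.5", "q97.5", "rhat", "ess")]
#>       parameter  mean   q2.5  q97.5 rhat   ess
#> 1   b_Intercept -1.53 -4.986  1.941 1.02  80.1
#> 2          b_x1  1.32 -0.117  3.238 1.01 769.2
#> 3          b_x2 -2.27 -4.463 -0.777 1.03 308.9
#> 4   sigma_phylo  3.23  1.019  8.295 1.10  62.3
#> 5 sigma_species  2.33  0.127  6.224 1.09  76.0
bayes_r2(fit, "marginal")$mean
#> [1] 0.194
bayes_r2(fit, "conditional")$mean
#> [1] 0.509
```

The true coefficients (1.5, −1) sit inside their 95% credible intervals;
the random-effect SDs carry the wide intervals binary data of this size
always give them, and the gap between marginal R² (fixed effects only,
0.19) and conditional R² (fixed plus random effects, 0.51) quantifies how
much of the trait's variation is carried by species identity and shared
ancestry rather than by the measured predictors.

The diversification and niche stages follow the same pattern:
`simulate_sse_dataset()` → `fit_sse_model_set()` →
`compare_sse_models()` / `sse_rate_summary()`, and `stochastic_maps()` →
`fit_niche_models()` → per-variable AICc tables.  `run_pipeline()` chains
all stages from a YAML config and writes CSV/JSON results plus a manifest
of seeds and input checksums.

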