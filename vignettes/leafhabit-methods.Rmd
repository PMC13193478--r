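---
title: "Models and methods behind leafhabit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafhabit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(leafhabit)
```

`leafhabit` asks three linked questions about a binary leaf-habit trait
(deciduous vs evergreen) on a time-calibrated phylogeny of a tropical plant
clade: did the trait shape diversification, and did that relationship change
through time; does the trait structure the evolution of the species'
environmental niches; and which present-day environmental variables predict
the trait across species.  This vignette documents the models, the
numerical choices, and the limits of what the test suite can show.

## Time-stratified state-dependent diversification

The diversification stage uses the standard state-dependent
speciation–extinction (SSE) machinery: each lineage carries a composite
state (observed leaf habit crossed with a two-level hidden state), with
per-state speciation rates $\lambda_s$, extinction rates $\mu_s$ and a
transition-rate matrix $Q$.  The likelihood solves the usual coupled
equations along each branch, backward in time $t$ (ages; tips at 0),

$$\frac{dE_s}{dt} = \mu_s - (\lambda_s + \mu_s + \textstyle\sum_j q_{sj})
E_s + \lambda_s E_s^2 + \textstyle\sum_j q_{sj} E_j,$$
$$\frac{dD_s}{dt} = -(\lambda_s + \mu_s + \textstyle\sum_j q_{sj}) D_s +
2 \lambda_s E_s D_s + \textstyle\sum_j q_{sj} D_j,$$

with $D$ multiplied by $\lambda$ at internal nodes and tips initialized
with per-state sampling fractions.  Every rate may differ between an
*early* epoch (ages above `slice_age`) and a *late* epoch; the boundary is
an explicit integration breakpoint with $D$ and $E$ continuous across it.

The model family crosses four flags: early and late speciation each either
*dependent* (rates vary by observed habit) or *independent* (rates vary by
the hidden state only — the character-independent null with the same number
of speciation parameters, so the dependent/independent contrast is not a
complexity contrast); symmetric vs asymmetric observed transitions; and
constant vs epoch-varying transition rates.  Two unstratified reference
models complete the set of 18.  Extinction is shared across composite
states within an epoch by default because the scientific question concerns
speciation; hidden-state transitions use a single symmetric rate (per epoch
when transitions are time-variable); dual transitions are forbidden.

Choices the user can change, with defaults:

* **Root treatment** — root state weights proportional to the normalized
  $D$ values (`"weighted"`); a flat option exists.  Survival conditioning
  on two surviving crown lineages is on by default.
* **Sampling fraction** — 0.6 per observed state (roughly the fraction of
  the genus sampled in the reference tree, 336 of c. 560 species); always
  report it, results can be sensitive to it.
* **Integration** — embedded Cash–Karp Runge–Kutta 4(5) with `rtol = 1e-8`,
  `atol = 1e-10`; $D$ is renormalized at every node with the log factor
  accumulated, so 300+ tip trees do not underflow.  Negative $D$ excursions
  are clipped and counted; the counter is zero in healthy runs.
* **Optimization** — bounded quasi-Newton (`nlminb`) on log rates in
  $[10^{-6}, 10]\,\mathrm{Myr^{-1}}$, with Latin-hypercube starting points
  (2 starts by default, mirroring the two-replicates-per-model protocol);
  all starts are retained for multimodality diagnosis.

## Niche evolution under regime paintings

The niche stage contrasts nine Gaussian models of a continuous
environmental trait under two selective regimes painted on the tree:
single- and multi-rate Brownian motion (BM1, BMV) and Ornstein–Uhlenbeck
models letting the rate $\sigma^2$, the pull $\alpha$, and/or the optimum
$\theta$ differ by regime (OU1, OUA, OUV, OUM, OUVA, OUMV, OUMVA).  Tip
means and covariances are computed exactly by propagating
$(m, v) \mapsto (\theta + (m-\theta)e^{-\alpha t},\;
v e^{-2\alpha t} + \sigma^2 (1 - e^{-2\alpha t})/(2\alpha))$ along each
branch segment, with between-tip covariance equal to the MRCA's variance
attenuated by $e^{-\int \alpha}$ down both descending paths.  The BM limit
is taken analytically when $\alpha = 0$ (and numerically guarded below
$10^{-12}$).

A full joint model of the discrete regime and the continuous trait would
marginalize over regime histories inside one likelihood.  This package
deliberately uses the classical two-step approximation instead: fit the
ARD Mk model for the regime trait once, draw stochastic character maps
(default 100, fixed seed), and average the Gaussian likelihood over maps by
log-mean-exp, holding the same maps fixed across all nine models and all
environmental variables.  The contrast of interest — *which* parameters
differ by regime — is preserved, every likelihood is fully specified by
code in this package, and model comparison stays internally consistent
because all models see identical maps.  The cost is that Akaike weights
need not match a joint-marginalization analysis exactly; weights for the
same data under the joint approach can differ by more than the usual
Monte-Carlo noise, and we document rather than hide this.

Parameter counts for AICc include the continuous parameters only (the
shared Mk rates are identical across compared models and cancel from the
contrast); $n$ is the number of species.  The root value is the root
regime's $\theta$ for OU models (a stationary-root option exists) and an
estimated ancestral mean for BM models.  Species' environmental values are
aggregated as the mean over their occurrence points (median available) and
z-scored across species before fitting.

## Occurrence and environment preparation

Occurrences are filtered to native-range polygons (winding-number
point-in-polygon test).  Species ranges are convex hulls of cleaned points;
degenerate hulls (fewer than three distinct or collinear points) are
buffered by one grid cell.  Species with at least 5 occurrence records use
their own (spatially thinned) points; species below that threshold get 20
random points drawn without replacement from the distinct cells of the
environmental grid inside their range polygon — "without replacement" is
defined over grid cells because the analysis grid (30 arc-seconds by
default) is the natural sampling frame.  Thinning enforces a 1.5 km
minimum haversine distance (mean Earth radius 6371.0088 km) by greedy
max-conflict removal with seeded tie-breaks; the exact maximum independent
set is used only as a test oracle.  Collinearity is screened by variance
inflation factors with the conventional threshold of 5; predictors are
mean-centered and scaled by two standard deviations so continuous and
binary predictors live on one scale.

## The phylogenetic multilevel model of leaf habit

Habit is modeled as Bernoulli with
$\operatorname{logit} P(y_i = 1) = \beta_0 + X_i\beta + a_i + u_i$, where
$a \sim \mathrm{MVN}(0, \sigma^2_{\mathrm{phylo}} C)$ for the tree-derived
correlation matrix $C$ and $u_i \sim N(0, \sigma^2_{\mathrm{species}})$ an
independent species effect.  Priors: $N(0, 2)$ for fixed effects,
Student-t(3, 0, 2.5) for the intercept, half-t(3, 0, 2.5) for the SDs.

Sampling is by an exact Pólya–Gamma Gibbs sampler: each Bernoulli
observation is augmented with $\omega_i \sim \mathrm{PG}(1, \eta_i)$
(Devroye's alternating-series sampler, written in C++ against R's RNG so
runs are bit-reproducible), which makes every conditional Gaussian or
inverse-gamma.  The half-t priors are represented by the Huang–Wand
inverse-gamma mixture, keeping the $\sigma^2$ updates conjugate, and each
SD is additionally re-drawn in the non-centered parameterization by slice
sampling (an interweaving step) — without it the centered Gibbs chain
mixes an order of magnitude more slowly on these weakly identified
variance components.  The centered conjugate block update plays the role a
non-centered Cholesky parameterization plays in gradient-based samplers;
$C$ gets a $10^{-10}$ diagonal jitter before factorization.  `adapt_delta`
has no analogue here: there is no step-size adaptation to tune, which is
one reason a Gibbs scheme was chosen.  Default settings mirror the
analysis protocol: 4 chains, 10 000 iterations each including 2 000
warmup, thinned by 10.  Convergence is summarized by split-$\hat R$ and an
autocorrelation-based effective sample size.

Bayesian $R^2$ is computed per draw on the probability scale,
$R^2 = \mathrm{Var}(p) / (\mathrm{Var}(p) + \overline{p(1-p)})$, with the
random effects zeroed (*marginal*) or included (*conditional*); a
latent-logit-scale variant sits behind a flag because the literature names
the quantity but not the scale.  Posterior predictive checks replicate the
response under conditional fitted probabilities.  Prior power-scaling
reweights the stored draws by $\mathrm{prior}^{\alpha-1}$ (or
$\mathrm{likelihood}^{\alpha-1}$) using the per-draw log prior of the
top-level parameters, and reports mean drift plus a symmetrized cumulative
Jensen–Shannon distance between base and scaled posteriors, flagged above
the conventional 0.05 cut; the effective sample size of the importance
weights guards against unreliable extrapolation.

## Synthetic data: what it emulates and what it does not

The generators produce data with exactly the statistical structure each
stage assumes: a Gillespie forward simulation of the four-composite-state
birth–death process with the epoch switch (conditioned on survival by
retry, which slightly biases against high-extinction histories — accepted
at test scale); exact Gaussian OU transition sampling along regime
paintings (no Euler error); the multilevel Bernoulli model with
controllable predictor correlation (e.g. the strong aridity–precipitation
correlation of real climate layers, $r = 0.93$); and smooth gradient-plus-
ripple environmental layers with clustered occurrence points and random
convex range polygons, including a configurable share of species with
fewer than five records to exercise the random-point path.

Generator defaults describe the study conditions the package targets: a
clade of a few hundred species (target 300, accepted range half to twice
that), crown age 30 Myr, epoch boundary 7 Ma, transitions toward
deciduousness frequent early (0.113 Myr⁻¹) and nearly absent late
(10⁻⁴ Myr⁻¹) with the reverse roughly constant (0.015/0.014 Myr⁻¹),
hidden-state speciation structure early (0.10 vs 0.25 Myr⁻¹) switching to
habit-dependent speciation late (evergreen 0.45 vs deciduous 0.18 Myr⁻¹).
Speciation and extinction magnitudes are not printed in the source
analyses, so these were chosen once as values a comparative study of this
scale could plausibly detect, and are not revisited.

Passing tests on these data show that the estimators recover the structure
they assume.  They do not show robustness to what real data add:
phylogenetic error and soft polytomies, spatial sampling bias and
coordinate error beyond thinning reach, niche measurement error (no
within-species variance term), or climate fields with realistic spatial
autocorrelation.

## Numerical conventions worth knowing

* Ultrametricity is checked to `1e-6 × root_age`; `normalize_depths()`
  repairs rounding-level spread only (refuses above 1% of height).
* Ties in spatial thinning and all stochastic-map draws are controlled by
  explicit seeds; every randomized routine is bit-reproducible.
* Singular OU tip covariances get a `1e-10` ridge with a warning.
* The stochastic-map rejection sampler caps at 1e5 attempts per branch and
  errors rather than silently degrading.
* Stage seeds in the pipeline are `seed + 1000 × stage index` (env, sse,
  niche, glmm), so any stage can be rerun alone.

## Problem sizes used by the checks

The packaged checks run recovery studies at 20 replicates with
200-tip trees for the diversification and regression stages and a
200-species niche study with 5 shared maps and 2 optimizer starts;
simulation-based calibration uses 200 reduced-length chains on a 30-tip
tree.  These sizes were chosen as the smallest at which the corresponding
contrasts are comfortably detectable, so the whole suite stays a
coffee-break run on a laptop core.

## Known limitations

* **Exact model identification by AIC is weak at realistic sizes.**  In
  the packaged recovery study, data simulated under the
  independent-early/dependent-late scenario almost always put *some*
  trait-dependent-speciation model on top, and the early-versus-late
  transition-rate ordering is recovered reliably, but the exact
  12-parameter generating configuration rarely attains the lowest AIC:
  with only a few dozen lineages alive in the early epoch, reduced
  variants (constant or symmetric transitions, or no time slice) fit
  nearly as well and win on parsimony.  Conclusions should therefore be
  drawn at the level of scenario families and rate contrasts, not of a
  single winning model — which is also how the per-epoch rate summaries
  are meant to be read.
* The niche stage's two-step approximation (above) is a deliberate
  departure from joint discrete–continuous marginalization.
* No cladogenetic state change, no more than two observed states, and no
  MCMC over SSE parameters.
* The Bernoulli $R^2$ depends on the predictor design through
  $\mathrm{Var}(p)$; comparisons across datasets are not meaningful.
* Growth form enters the regression only as scaled dummy columns; no
  interactions are modeled.
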