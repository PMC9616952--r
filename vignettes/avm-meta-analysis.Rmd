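---
title: "Phylogenetic meta-analysis of at-vessel mortality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic meta-analysis of at-vessel mortality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

At-vessel mortality (AVM) is the proportion of caught animals that are dead
when pelagic longline gear is retrieved, before any handling by crew. For
sharks and rays this quantity drives bycatch policy: species that usually
arrive dead need measures that reduce catch itself, while species that
usually arrive alive benefit from handling-and-release rules and retention
bans. Published AVM evidence is scattered across many studies, each
reporting deaths out of total caught for one species under particular gear
and ocean conditions, with study sizes ranging from a handful of animals to
thousands.

`avmmeta` synthesises such evidence. One *effect size* is a record
`(n_dead, n_caught)` for one species in one study, together with moderators
(ocean basin, hook shape and type, hooks between floats, soak duration,
bait type, body form, ventilation mode) and grouping identifiers (study,
record within study, research group). Because related shark species share
physiology and behaviour that plausibly affect survival on a line, species
cannot be treated as independent: the package adjusts for shared
evolutionary history through a phylogeny.

## The model

The core model is a binomial-Normal hierarchical meta-regression. For
record $i$ of species $s(i)$ in study $j(i)$ and research group $g(i)$:

$$x_i \sim \mathrm{Binomial}(n_i, p_i)$$
$$\operatorname{logit}(p_i) = \beta_0 + \mathbf{x}_i^\top \boldsymbol\beta
  + f(z_i) + u^{sp}_{s(i)} + u^{st}_{j(i)} + u^{rec}_i + u^{grp}_{g(i)}$$

with an exact binomial within-record likelihood (no normal approximation of
the proportions) and Normal random effects on the logit scale:

* **species**: $\mathbf{u}^{sp} \sim \mathrm{MVN}(0,\,
  \sigma^2_{phylo}\, C)$, where $C$ is the Brownian-motion correlation
  implied by the phylogeny — the shared root-to-ancestor path length of two
  species divided by $\sqrt{d_i d_j}$ of their root-to-tip depths. An
  ultrametric tree gives the familiar shared-path/total-depth fraction; a
  star phylogeny gives the identity matrix (no adjustment). The
  normalisation with $\sqrt{d_i d_j}$ is used because empirical
  (fossil-calibrated) trees are not always exactly ultrametric; it reduces
  to the standard form when they are. There is deliberately **no**
  additional iid species effect: the phylogenetic term *is* the species
  term, so the variance partition below is well defined.
* **study**, **record-within-study**, **research group**: independent
  $N(0, \sigma^2_k)$. The record-level effect absorbs overdispersion
  relative to the binomial; the research-group effect absorbs clustering of
  studies produced by the same team.

Categorical moderators are treatment-coded against the alphabetically
first level; records with unknown moderator values keep an explicit
`"unknown"` level rather than being dropped, so the fitted data are exactly
the loaded data. Continuous covariates (hooks between floats, optionally
soak duration) enter as penalized cubic B-spline smooths with `spline_k`
(default 10) basis functions and a second-difference penalty, expressed in
mixed-model (Demmler–Reinsch) form: an unpenalised linear column plus
independent Normal basis coefficients with their own standard deviation.
This is the same smoothing class as thin-plate bases at these covariate
resolutions, and the mixed-model form means the smoothness penalty is just
another variance parameter estimated with everything else.

### Priors

All priors are weakly informative and configurable via `avm_priors()`:
Student-t(3, 0, 2.5) on the intercept (logit scale), Normal(0, 2) on fixed
effects and spline linear terms, half-Student-t(3, 0, 2.5) on every
standard deviation. On the probability scale the implied prior for a
typical record is close to uniform with mild shrinkage away from 0 and 1;
prior predictive checks in the test suite confirm the induced pooled rate
is not concentrated anywhere in (0, 1).

### Sampling and parametrization

Posteriors are drawn by MCMC through JAGS (Gibbs/slice updates, with the
`glm` module's blocked conjugate updates for the linear-Gaussian parts).
Two details matter in practice:

* The species effect uses a **centered** parametrization: species
  intercepts $a_s \sim \mathrm{MVN}(\beta_0 \mathbf{1},\,
  \sigma^2_{phylo} C)$ via the precision matrix $C^{-1}/\sigma^2_{phylo}$.
  With tens of records per species the centered form mixes far better
  under Gibbs than the scaled-Cholesky (non-centered) form, whose
  intercept/species-mean confounding produces severe autocorrelation; the
  recovery tests run at the short `ci` profile only because of this
  choice.
* A jitter of `1e-8` is added to the diagonal of $C$ before inversion or
  factorization (documented constant, `avmmeta:::avm_chol_jitter()`).

Two sampler profiles are provided. `avm_sampler("paper")` runs 4 chains ×
10,000 post-warmup iterations after 2,000 warmup — the configuration for a
full analysis. `avm_sampler("ci")` runs 4 × 500 after 500 warmup, which is
what the test-suite recovery studies use; at that length a few variance
parameters can sit slightly above the Rhat < 1.01 criterion, which is why
`fit_avm()` reports convergence as a flag on the fit rather than failing.
Chain RNG seeds derive deterministically from the sampler seed, so a fit is
bit-reproducible.

### Posterior summaries

All reported uncertainty uses the **highest density interval** — the
narrowest window of sorted draws containing the target mass (ties broken
toward the lower window; never wider than the equal-tailed interval). The
**probability of direction** is the posterior mass of the majority sign,
with draws exactly at zero split evenly.

* `pooled_avm()` reports, per draw, the population-level rate (group
  effects at zero) averaged over the observed moderator configurations with
  weights proportional to record sample size (`n_caught`); `weights =
  "equal"` switches to an unweighted reference grid.
* `species_avm()` adds each species' phylogenetic effect before averaging,
  giving conditional species-specific rates sorted ascending.
* `phylo_signal()` computes per draw
  $\lambda = \sigma^2_{phylo} / \sum_k \sigma^2_k$ over the four
  group-level variances — the proportion of hierarchical variance
  attributable to shared ancestry. Every draw lies in $[0, 1]$ by
  construction.
* `marginal_means()` and `ratio_contrast()` give moderator-level predicted
  rates and their ratios (e.g. how many times more likely a capture is to
  be dead in one ocean basin than another), again on the proportional- or
  equal-weight reference grid.

Model comparison uses PSIS-LOO (Pareto-smoothed importance sampling
leave-one-out) computed from the pointwise binomial log-likelihood, with
generalized-Pareto tail smoothing and the shape diagnostic $\hat k$;
stacking weights maximise the leave-one-out log score over the simplex.
Convergence is monitored with rank-normalized split-Rhat and bulk/tail
effective sample sizes. Note that leave-one-*record*-out conditions on the
record-level effect, as is standard for hierarchical binomial models.

## Moderator screening and imputation

Putting every extracted moderator into the regression invites overfitting,
so a machine-learning screen runs first (`screen_predictors()`): random
forests on the continuity-corrected logit proportion
$\tilde p_i = (x_i + 0.5)/(n_i + 1)$, with case weights
$1/(v_i + \hat\tau^2)$ (delta-method logit variance plus a
DerSimonian–Laird between-study variance — a deterministic, closed-form
choice appropriate for a filter rather than an inference target), and a
clustered bootstrap that resamples whole studies. Importance is mean
permutation importance across replicates rescaled to a percent-of-maximum
scale; the default cut-off flags predictors above 10% of the top
predictor. Hyperparameters (500 trees, $mtry = \lceil\sqrt p\rceil$,
minimum node size 5, 100 replicates) are ordinary random-forest defaults.
Taxonomic predictors (genus/family/order) are screened but then excluded
from the regression fixed effects by `screened_moderators()` — the
phylogenetic term models that structure explicitly, and keeping both would
double-count it. The continuity correction exists only in this screening
(and funnel) stage; the Bayesian model uses the exact binomial likelihood.

Gear moderators arrive incomplete (typically a few percent of hooks
-between-floats and over ten percent of soak durations).
`impute_missing()` chains random forests column-by-column until the summed
out-of-bag error stops improving, with **predictive mean matching** for
numeric columns: each missing cell receives the observed value of one of
the `pmm_donors` (default 5) records whose predictions are closest, so no
value that was never observed can be imputed. Observed cells are never
altered — the test suite asserts exact equality over the non-missing mask.
A single completed dataset is produced, not a multiple-imputation pool.

## Sparse species

Species with too few records for a regression (default: fewer than 5,
configurable in `sparse_species_table()`) — including species with zero
recorded deaths — are summarised by pooling their counts and applying a
binomial likelihood with the uniform Bayes–Laplace Beta(1, 1) prior. The
posterior is Beta(x+1, n−x+1) with mean $(x+1)/(n+2)$, strictly inside
(0, 1) even at $x = 0$ or $x = n$; the 95% HDI is found by direct 1-D
optimisation over the interval's lower endpoint (a Monte-Carlo path is
retained purely as a cross-check and agrees to sampling error). The exact
routing rule for which species are "too sparse" is a judgement call; the
record-count threshold is exposed as an argument rather than hard-coded.

## Publication bias

`funnel_analysis()` builds a contour-enhanced funnel on the
continuity-corrected logit effects: shaded regions mark where a record
would be individually significant at two-sided p = 0.10/0.05/0.01, widening
linearly with the standard error and meeting the zero reference exactly at
SE = 0. The pooled line comes from a frequentist REML random-effects fit
with records nested in studies (metafor's multivariate parameterisation),
and asymmetry is tested Egger-style — meta-regressing effect on standard
error — with cluster-robust standard errors at the study level. This is a
deliberate simplification relative to carrying the full phylogenetic
random-effect structure into the frequentist fit: the diagnostic is
qualitative, and the cluster-robust approximation preserves both the funnel
geometry and the asymmetry inference (type-I error and power are verified
against generators with and without suppression in the acceptance tests).

## The synthetic-data generator

`simulate_avm()` exists so every stage is testable against known truth
without any external data. It generates exactly the structure the model
assumes: a unit-depth pure-birth (Yule) tree (or star tree), species
effects drawn MVN(0, $\sigma^2_{phylo} C$), iid study / record / research
-group effects, a treatment-coded ocean effect assigned **per study** (as
in real fleets, where a study works one basin), a sinusoidal
hooks-between-floats effect of amplitude 0.3 on the logit scale (large
enough to exercise the spline, small enough not to dominate the fixed
effects), negative-binomial catch sizes (mean 30, dispersion 1.2 — a
long-tailed distribution matching the heavy skew of real per-study catch
counts), and binomial deaths. Defaults are sized like a 13-species clade
analysis: ~460 records over 40 studies in 6 research groups, baseline
mortality 0.35, $\beta_{ocean} = 1$, $\sigma_{phylo} = 0.8$,
$\sigma_{study} = 0.5$, $\sigma_{record} = 0.3$, $\sigma_{group} = 0.3$.

Gear moderators are generated with realistic dependence: hooks between
floats is a per-study base level with record-level jitter, and soak
duration co-varies with it (deeper-set gear soaks longer). This dependence
is what makes imputation meaningful — under fully independent moderators no
imputer can beat the marginal mean. Missingness is MCAR at 4% (hooks
between floats) and 14% (soak duration) by default, with the masks and the
full pre-masking values recorded in the returned truth object.

What the generator does **not** emulate: reporting bias at the study level
(except the suppression scenario constructed in the publication-bias
tests), moderator effects that differ between species, measurement error in
the moderators, non-MCAR missingness, and phylogenetic uncertainty (one
tree per dataset). Passing recovery tests on these simulations therefore
demonstrates that the estimation machinery is correct and calibrated under
the model's own assumptions — not that real longline data satisfy those
assumptions.

## Validation strategy and problem sizes

The test suite checks each component against an independent oracle:
closed-form Beta posteriors and dense-grid HDI scans for the sparse
estimator, brute-force ancestor-set traversal for the Brownian correlation,
an independently coded rank-normalized split-Rhat, exact Beta-binomial
leave-one-out for PSIS-LOO, a conjugate single-record posterior for the
fitted model, and an iid-species reformulation for the identity-correlation
case. The recovery study refits five seeded 13-species/~460-record
datasets at the `ci` sampler profile and requires the 95% HDIs to cover
$\beta_{ocean}$, $\sigma_{phylo}$ and $\sigma_{study}$ in at least four of
five replicates, plus a null scenario in which the signal HDI must
concentrate below 0.3; `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed. These replicate counts and the
reduced sampler profile are the package's standing choices for routine
validation; the same properties can be (and were, during development)
checked at larger sizes with the `paper` profile.

## Known limitations

* The JAGS backend monitors record-level probabilities, so `paper`-profile
  fits on several hundred records hold a few hundred MB of draws in memory.
* PSIS-LOO is leave-one-record-out; leave-one-study-out would require
  refitting and is not implemented.
* The funnel asymmetry test approximates the fully structured multivariate
  fit with study-level cluster-robust errors (see above).
* Single-tree conditioning: uncertainty in the phylogeny is addressed by
  sensitivity reruns over `select_tree()` indices, not by model averaging.
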