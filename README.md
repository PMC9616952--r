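# avmmeta

Phylogenetically adjusted Bayesian meta-analysis of **at-vessel mortality
(AVM)** — the proportion of caught animals dead when fishing gear is
retrieved — for sharks and rays in pelagic longline fisheries.

Bycatch policy hinges on species-specific AVM rates: species that usually
arrive dead need measures that reduce catch itself (effort controls, gear
selectivity), while species that usually arrive alive benefit from
handling-and-release practices and retention bans. Evidence is scattered
over many studies of very different sizes, and related shark species share
traits that shape their survival on a line, so records are neither
independent across species nor exchangeable across studies. `avmmeta`
synthesises such evidence with a **binomial-Normal hierarchical
meta-regression**:

    x_i ~ Binomial(n_i, p_i)
    logit(p_i) = b0 + X_i B + f(z_i) + u_species[s(i)] + u_study[j(i)]
                 + u_record[i] + u_group[g(i)]

with an exact binomial within-record likelihood, categorical moderators
(ocean basin, hook shape/type, bait type, ...), penalized-spline smooths
for continuous gear covariates (hooks between floats, soak duration), and
Normal random effects for study, record-within-study and research group.
The species effects are multivariate Normal with the **Brownian-motion
correlation matrix C** derived from a phylogeny, and the **phylogenetic
signal** is reported as the posterior proportion of summed group-level
variance attributable to that term:

    lambda = sigma2_phylo / (sigma2_phylo + sigma2_study + sigma2_record + sigma2_group)

Around the core model the package provides the full workflow: CSV data
model with validation and clade/ocean subsetting, Newick/NEXUS tree
handling, random-forest moderator screening with meta-analytic weights and
clustered bootstrap, chained random-forest imputation with predictive mean
matching, highest-density-interval and probability-of-direction summaries,
sample-size-weighted marginal means and risk ratios, PSIS-LOO model
comparison with stacking, posterior predictive checks, Bayes-Laplace
estimation for data-poor species (robust to zero recorded deaths),
contour-enhanced funnel diagnostics for publication bias, forest plots,
and a synthetic-data generator with known truth that makes every stage
testable offline. See the methods vignette
(`vignettes/avm-meta-analysis.Rmd`) for the modelling details and design
rationale.

## Worked example

Simulate a clade-scale dataset with known truth (13 species on a Yule
tree, ~460 records, true ocean effect 1.0 on the logit scale, true
sigma_phylo = 0.8 implying lambda ~ 0.60), impute the masked gear
covariates, fit the phylogenetic model, and summarise:

```r
library(avmmeta)

sim  <- simulate_avm(seed = 42)                 # data + truth
dat  <- impute_missing(sim$data, seed = 42)     # fill 4% / 14% MCAR gaps
spec <- avm_model_spec(
  fixed = "ocean", spline = "hooks_between_floats",
  sampler = avm_sampler("ci", seed = 42))       # 4 x 500 test profile
fit  <- fit_avm(dat, spec, tree = sim$truth$tree)

pooled_avm(fit)
#>   quantity    mean hdi_lower hdi_upper
#> 1 pooled_avm 0.511     0.283     0.742

phylo_signal(fit)
#>   quantity      mean hdi_lower hdi_upper
#> 1 phylo_signal 0.633     0.384     0.843

ratio_contrast(fit, "ocean", "Pacific", "Atlantic")
#>   quantity                   mean hdi_lower hdi_upper prob_gt_1
#> 1 ocean: Pacific / Atlantic  1.65      1.21      2.14         1

head(species_avm(fit), 3)
#>   species           mean hdi_lower hdi_upper
#> 1 Parasynthus sp08 0.284     0.205     0.374
#> 2 Synthus sp07     0.300     0.218     0.379
#> 3 Parasynthus sp12 0.357     0.270     0.453
```

Reading the output: the pooled rate (0.51, 95% HDI 0.28–0.74) is the
sample-size-weighted population-level mortality with all group effects at
zero; the signal estimate says about 63% of the hierarchical variance in
this replicate is attributable to shared ancestry (the generating value is
0.60); and captures in the Pacific are about 1.7 times as likely to be
dead at haulback as in the Atlantic (the generator's ocean effect), with
posterior probability ~1 that the ratio exceeds 1. Species-specific rates
come back sorted ascending with their HDIs.

Data-poor species with zero observed deaths still get a usable estimate
via the Bayes-Laplace binomial estimator — for 0 dead of 18 caught:

```r
bayes_laplace_estimate(0, 18)
#>   x  n mean hdi_lower hdi_upper
#> 1 0 18 0.05         0     0.146
```

Real data enter through `read_avm()` (CSV with a configurable column
mapping), `subset_clade()` (one taxonomic order, chosen ocean basins) and
`read_phylo()`/`select_tree()` (Newick or NEXUS, multi-tree sets);
`replicate_clade_analysis()` chains those stages into one call, and
`run_avm_pipeline()` drives the whole workflow (screen, impute, fit,
summarise, funnel) from a single config with a reproducible run manifest.
`tidy()`, `glance()`, `autoplot()`, `plot_species_avm()` and
`forest_plot()` cover inspection and figures.

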