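# helper: sd draws by name
flat_sigma <- function(fit, par) as.numeric(fit$draws[, , par])

test_that("intercept-only single-record posterior matches the conjugate Beta", {
  df <- tiny_avm_df()[1, ]
  df$n_caught <- 8L
  df$n_dead <- 3L
  spec <- avm_model_spec(fixed = character(0), spline = character(0),
                         phylo = FALSE, group = character(0),
                         sampler = avm_sampler("ci", chains = 2, iter = 2000,
                                               warmup = 500, seed = 31))
  fit <- fit_avm(as_avm(df), spec)
  p_mean <- mean(fit$p)
  # Beta(4, 6) posterior under a flat prior has mean 0.4; the weakly
  # informative logit-scale prior shifts this only slightly
  expect_lt(abs(p_mean - 0.4), 0.05)
})

test_that("fitting is seed-reproducible", {
  sim <- small_sim()
  spec <- avm_model_spec(fixed = "ocean", spline = character(0),
                         sampler = avm_sampler("ci", chains = 2, iter = 150,
                                               warmup = 150, seed = 77))
  f1 <- fit_avm(sim$data, spec, tree = sim$truth$tree)
  f2 <- fit_avm(sim$data, spec, tree = sim$truth$tree)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$p, f2$p)
})

test_that("identity-correlation species effect matches an iid species route", {
  # route A: phylogenetic machinery with C = identity
  # route B: same model expressed with species as an iid grouping factor
  sim <- simulate_avm(n_species = 6, n_studies = 10,
                      records_per_study = c(6, 8), sigma_study = 0,
                      sigma_group = 0, sigma_record = 0.3,
                      miss_hbf = 0, miss_soak = 0,
                      tree = simulate_tree(6, "star"), seed = 55)
  df <- sim$data
  samp <- avm_sampler("ci", chains = 2, iter = 800, warmup = 400, seed = 13)
  ident <- diag(length(unique(df$species)))
  dimnames(ident) <- list(sort(unique(df$species)), sort(unique(df$species)))
  fitA <- fit_avm(df, avm_model_spec(fixed = "ocean", spline = character(0),
                                     phylo = TRUE, group = "record",
                                     sampler = samp), corr = ident)

  dfB <- df
  dfB$study_id <- dfB$species       # species as iid grouping
  fitB <- fit_avm(dfB, avm_model_spec(fixed = "ocean", spline = character(0),
                                      phylo = FALSE,
                                      group = c("study", "record"),
                                      sampler = samp))
  # posterior means agree within Monte-Carlo error
  expect_equal(mean(fitA$p), mean(fitB$p), tolerance = 0.02)
  expect_equal(mean(flat_sigma(fitA, "sigma_phylo")),
               mean(flat_sigma(fitB, "sigma_study")), tolerance = 0.12)
  expect_equal(colMeans(fitA$p), colMeans(fitB$p), tolerance = 0.05)
})

test_that("removing a group term never increases the parameter count", {
  sim <- small_sim()
  samp <- avm_sampler("ci", chains = 2, iter = 100, warmup = 100, seed = 5)
  full <- fit_avm(sim$data, avm_model_spec(
    fixed = "ocean", spline = character(0), sampler = samp),
    tree = sim$truth$tree)
  reduced <- fit_avm(sim$data, avm_model_spec(
    fixed = "ocean", spline = character(0), group = "study",
    sampler = samp), tree = sim$truth$tree)
  expect_lte(dim(reduced$draws)[3], dim(full$draws)[3])
})

test_that("model preconditions are enforced", {
  df <- as_avm(tiny_avm_df())
  expect_error(fit_avm(df[df$species == "Synthus sp01", ],
                       avm_model_spec(fixed = character(0),
                                      spline = character(0))),
               ">= 2 species")
  expect_error(fit_avm(df, avm_model_spec(fixed = character(0),
                                          spline = character(0))),
               "tree or corr")
  expect_error(avm_model_spec(sampler = avm_sampler(chains = 1)),
               "2 chains")
  expect_error(avm_model_spec(fixed = "ocean",
                              interactions = "ocean:hook_type"),
               "interaction")
  # spline covariate with missing values demands imputation first
  dfna <- tiny_avm_df()
  dfna$hooks_between_floats[2] <- NA
  expect_error(fit_avm(as_avm(dfna),
                       avm_model_spec(fixed = character(0), phylo = FALSE,
                                      group = character(0))),
               "impute")
})

test_that("posterior predictive replicates respect the data contract", {
  fit <- small_fit()
  ppc <- posterior_predictive_check(fit, n_rep = 50, seed = 3)
  expect_equal(ncol(ppc$rep_props), 50)
  expect_true(all(ppc$rep_props >= 0 & ppc$rep_props <= 1))
  # self-consistency: data were generated by the same hierarchical process
  # the model assumes, so the observed summary sits inside the replicated band
  expect_gt(ppc$observed_stats$mean_prop,
            quantile(ppc$rep_stats$mean_prop, 0.005))
  expect_lt(ppc$observed_stats$mean_prop,
            quantile(ppc$rep_stats$mean_prop, 0.995))
  expect_error(posterior_predictive_check(fit, n_rep = 0), "n_rep")
})

test_that("an injected outlier species falls outside its replicated band", {
  fit <- small_fit()
  df <- fit$data
  tweak <- df$species == df$species[1]
  df$n_dead[tweak] <- df$n_caught[tweak]      # force p ~ 1 for one species
  ppc <- posterior_predictive_check(fit, df = df, n_rep = 200, seed = 4)
  row <- ppc$species[ppc$species$species == df$species[1], ]
  expect_false(row$inside)
})

test_that("model spec serializes and restores", {
  spec <- avm_model_spec(fixed = c("ocean", "hook_shape"),
                         interactions = "ocean:hook_shape",
                         sampler = avm_sampler("ci", seed = 42))
  path <- tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$fixed, spec$fixed)
  expect_equal(back$interactions, spec$interactions)
  expect_equal(back$sampler$seed, spec$sampler$seed)
  expect_equal(back$priors, spec$priors)
})

test_that("default priors are weakly informative on the probability scale", {
  # prior predictive of a record-level rate under the default priors:
  # spread across (0,1), median near one half
  set.seed(41)
  pr <- avm_priors()
  b0 <- rt(20000, pr$intercept_df) * pr$intercept_scale
  p <- plogis(b0)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(quantile(p, 0.001), 0)      # essentially no mass collapsed to 0/1
  expect_lt(quantile(p, 0.999), 1)
  expect_lt(abs(median(p) - 0.5), 0.02)
  expect_gt(mean(p < 0.1) + mean(p > 0.9), 0.1)   # mass near both extremes
})
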