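test_that("pooled and species rates live on the response scale", {
  fit <- small_fit()
  pool <- pooled_avm(fit)
  expect_true(pool$mean > 0 && pool$mean < 1)
  expect_true(pool$hdi_lower <= pool$hdi_upper)
  expect_true(all(attr(pool, "draws") > 0 & attr(pool, "draws") < 1))

  sp <- species_avm(fit)
  expect_equal(nrow(sp), 8)
  expect_true(all(sp$mean >= 0 & sp$mean <= 1))
  expect_true(!is.unsorted(sp$mean))          # ascending order
  expect_error(species_avm(fit, species = "Ghostus sp99"), "not in fit")
})

test_that("phylogenetic signal draws are proportions", {
  fit <- small_fit()
  sig <- phylo_signal(fit)
  d <- attr(sig, "draws")
  expect_true(all(d >= 0 & d <= 1))
  expect_true(sig$hdi_lower <= sig$hdi_upper)
  # invariant to relabeling the non-phylogenetic variance components:
  # lambda only depends on the pooled non-phylo variance
  s2 <- flat_draws(fit, c("sigma_phylo", "sigma_study", "sigma_record",
                          "sigma_group"))^2
  lam_swapped <- s2[, "sigma_phylo"] /
    (s2[, "sigma_phylo"] + s2[, "sigma_group"] + s2[, "sigma_record"] +
       s2[, "sigma_study"])
  expect_equal(unname(d), unname(lam_swapped))
})

test_that("marginal means average the reference grid with the stated weights", {
  fit <- small_fit()
  mm <- marginal_means(fit, "ocean")
  expect_equal(sort(mm$level), c("Atlantic", "Pacific"))
  expect_true(all(mm$mean > 0 & mm$mean < 1))
  expect_error(marginal_means(fit, "bait_type"), "not in model")

  # equal weights are invariant to duplicating a data row; proportional
  # weights are not
  fit2 <- fit
  fit2$data <- dplyr::bind_rows(fit$data, fit$data[rep(1, 25), ])
  eq1 <- marginal_means(fit, "ocean", weights = "equal")
  eq2 <- marginal_means(fit2, "ocean", weights = "equal")
  expect_equal(eq1$mean, eq2$mean, tolerance = 1e-12)
  pr1 <- marginal_means(fit, "ocean", weights = "proportional")
  pr2 <- marginal_means(fit2, "ocean", weights = "proportional")
  expect_false(isTRUE(all.equal(pr1$mean, pr2$mean, tolerance = 1e-8)))
})

test_that("single-moderator marginal means equal level-specific fits", {
  sim <- small_sim()
  spec <- avm_model_spec(fixed = "ocean", spline = character(0),
                         phylo = FALSE, group = character(0),
                         sampler = avm_sampler("ci", chains = 2, iter = 300,
                                               warmup = 200, seed = 17))
  fit <- fit_avm(sim$data, spec)
  mm <- marginal_means(fit, "ocean")
  b0 <- as.numeric(fit$draws[, , "b0"])
  bp <- as.numeric(fit$draws[, , "oceanPacific"])
  expect_equal(mm$mean[mm$level == "Atlantic"], mean(plogis(b0)),
               tolerance = 1e-10)
  expect_equal(mm$mean[mm$level == "Pacific"], mean(plogis(b0 + bp)),
               tolerance = 1e-10)
})

test_that("ratio contrasts behave like ratios", {
  fit <- small_fit()
  same <- ratio_contrast(fit, "ocean", "Atlantic", "Atlantic")
  expect_equal(attr(same, "draws"), rep(1, same$n_draws))
  expect_equal(same$mean, 1)

  rc <- ratio_contrast(fit, "ocean", "Pacific", "Atlantic")
  inv <- ratio_contrast(fit, "ocean", "Atlantic", "Pacific")
  expect_equal(attr(rc, "draws"), 1 / attr(inv, "draws"), tolerance = 1e-12)
  expect_true(rc$prob_gt_1 >= 0 && rc$prob_gt_1 <= 1)
  expect_error(ratio_contrast(fit, "ocean", "Atlantic", "Arctic"),
               "no such level")
})

test_that("forest plot orders records and carries a pooled row", {
  df <- as_avm(tibble::tibble(
    record_id = paste0("r", 1:5), study_id = paste0("s", 1:5),
    species = "Synthus sp01", genus = "Synthus", family = "Synthidae",
    order = "Synthiformes",
    n_caught = c(20L, 30L, 25L, 40L, 15L),
    n_dead = c(2L, 18L, 10L, 35L, 5L),
    bait_type = c("squid", "squid", "fish", "fish", "mixed")
  ))
  fr <- forest_plot(df)
  expect_equal(sum(fr$table$row_type == "record"), 5)
  expect_equal(sum(fr$table$row_type == "pooled"), 1)
  recs <- fr$table[fr$table$row_type == "record", ]
  expect_false(is.unsorted(recs$log_rr))
  expect_s3_class(autoplot(fr), "ggplot")

  # split panels pool separately
  fr2 <- forest_plot(df, split_by = "bait_type")
  expect_equal(nrow(fr2$pooled), 3)

  expect_error(forest_plot(df[1, , drop = FALSE]), "at least 2")
  two_sp <- as_avm(tiny_avm_df())
  expect_error(forest_plot(two_sp), "single-species")
})

test_that("model-based pooled row equals pooled_avm on the same fit", {
  sim <- small_sim()
  one <- sim$data[sim$data$species == sim$data$species[1], ]
  spec <- avm_model_spec(fixed = character(0), spline = character(0),
                         phylo = FALSE, group = "study",
                         sampler = avm_sampler("ci", chains = 2, iter = 200,
                                               warmup = 200, seed = 23))
  fit <- fit_avm(one, spec)
  fr <- forest_plot(one, fit = fit)
  expect_equal(fr$pooled$p_pool, pooled_avm(fit)$mean)
})

test_that("tidiers and plots expose the fit", {
  fit <- small_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "hdi_lower", "rhat") %in% names(td)))
  expect_true("sigma_phylo" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_records, nrow(fit$data))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_species_avm(fit), "ggplot")
})
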