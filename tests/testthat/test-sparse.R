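# independent oracle: narrowest 95% interval of a Beta by a two-pointer
# scan of the CDF over a dense grid
grid_beta_hdi <- function(a, b, mass = 0.95, step = 1e-5) {
  x <- seq(0, 1, by = step)
  Fx <- pbeta(x, a, b)
  best <- c(0, 1)
  j <- 1L
  for (i in seq_along(x)) {
    while (j <= length(x) && Fx[j] - Fx[i] < mass) j <- j + 1L
    if (j > length(x)) break
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  best
}

test_that("Bayes-Laplace posterior mean is exact for all small counts", {
  for (n in 1:50) {
    x <- 0:n
    got <- vapply(x, function(xx) bayes_laplace_estimate(xx, n)$mean,
                  numeric(1))
    expect_equal(got, (x + 1) / (n + 2))
  }
  expect_equal(bayes_laplace_estimate(0, 18)$mean, 0.05)
})

test_that("boundary cases attach the HDI to the support edge", {
  all_dead <- bayes_laplace_estimate(12, 12)
  expect_equal(all_dead$mean, 13 / 14)
  expect_equal(all_dead$hdi_upper, 1)
  none <- bayes_laplace_estimate(0, 12)
  expect_equal(none$hdi_lower, 0)
  expect_gt(none$hdi_upper, 0)
  expect_error(bayes_laplace_estimate(5, 3), "x must")
  expect_error(bayes_laplace_estimate(1, 0), "n must")
})

test_that("Beta HDI matches a dense grid search", {
  for (case in list(c(3, 10), c(1, 18), c(8, 12), c(2, 2))) {
    est <- bayes_laplace_estimate(case[1], case[2])
    oracle <- grid_beta_hdi(case[1] + 1, case[2] - case[1] + 1)
    expect_lt(abs(est$hdi_lower - oracle[1]), 1e-3)
    expect_lt(abs(est$hdi_upper - oracle[2]), 1e-3)
  }
})

test_that("Monte-Carlo path agrees with the exact path", {
  ex <- bayes_laplace_estimate(3, 10)
  mc <- bayes_laplace_estimate(3, 10, method = "draws", n_draws = 50000,
                               seed = 5)
  expect_equal(mc$hdi_lower, ex$hdi_lower, tolerance = 0.02)
  expect_equal(mc$hdi_upper, ex$hdi_upper, tolerance = 0.02)
  # exact path is deterministic
  expect_identical(bayes_laplace_estimate(3, 10), ex)
})

test_that("posterior mean shrinks the raw proportion toward 1/2", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    m <- bayes_laplace_estimate(x, n)$mean
    raw <- x / n
    if (raw < 0.5) expect_true(m > raw && m < 0.5)
    if (raw > 0.5) expect_true(m < raw && m > 0.5)
    if (raw == 0.5) expect_equal(m, 0.5)
  }
})

test_that("interior HDIs contain the posterior mode", {
  for (case in list(c(3, 10), c(5, 40), c(20, 30))) {
    a <- case[1] + 1; b <- case[2] - case[1] + 1
    est <- bayes_laplace_estimate(case[1], case[2])
    mode <- (a - 1) / (a + b - 2)
    expect_true(est$hdi_lower <= mode && mode <= est$hdi_upper)
  }
})

test_that("species records pool to simple sums", {
  df <- as_avm(tiny_avm_df())
  xn <- pool_species_records(df, "Synthus sp01")
  expect_equal(unname(xn), c(5 + 3, 20 + 15))
  one <- pool_species_records(df, "Parasynthus sp03")
  expect_equal(unname(one), c(55, 65))
  expect_error(pool_species_records(df, "Missingus sp99"), "not in data")

  # oracle: independent aggregation over the raw table
  agg <- aggregate(cbind(n_dead, n_caught) ~ species, data = tiny_avm_df(),
                   FUN = sum)
  for (sp in agg$species) {
    expect_equal(unname(pool_species_records(df, sp)),
                 c(agg$n_dead[agg$species == sp],
                   agg$n_caught[agg$species == sp]))
  }
})

test_that("sparse table routes only under-sampled species", {
  df <- as_avm(tiny_avm_df())
  tab <- sparse_species_table(df, min_records = 3)       # all have 2 records
  expect_equal(sort(tab$species), sort(unique(df$species)))
  expect_true(all(tab$mean > 0 & tab$mean < 1))
  none <- sparse_species_table(df, min_records = 1)
  expect_equal(nrow(none), 0)
  named <- sparse_species_table(df, species = "Synthus sp02")
  expect_equal(named$x, 12L)
  expect_equal(named$n, 40L)
})
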