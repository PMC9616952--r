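#' Bayes-Laplace estimate of a binomial mortality proportion
#'
#' For data-poor species (including those with zero recorded deaths) the
#' at-vessel mortality rate is estimated from the pooled counts under a
#' binomial likelihood with a uniform Beta(1, 1) (Bayes-Laplace) prior, so
#' the posterior is Beta(x + 1, n - x + 1) with mean `(x + 1) / (n + 2)`,
#' strictly inside (0, 1) even when `x = 0` or `x = n`. The 95% highest
#' density interval is found by direct 1-D optimisation over the lower
#' endpoint of the Beta density (a Monte-Carlo path over posterior draws is
#' retained for cross-checking).
#'
#' @param x dead count (0 <= x <= n).
#' @param n caught count (>= 1).
#' @param mass HDI mass, default 0.95.
#' @param method `"exact"` (optimisation, deterministic) or `"draws"`.
#' @param n_draws Monte-Carlo draws for `method = "draws"`.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param species optional species label carried into the output.
#' @return one-row tibble: species, x, n, mean, hdi bounds, method.
#' @export
bayes_laplace_estimate <- function(x, n, mass = 0.95,
                                   method = c("exact", "draws"),
                                   n_draws = 10000, seed = 1,
                                   species = NA_character_) {
  method <- match.arg(method)
  if (n < 1) abort("n must be >= 1")
  if (x < 0 || x > n) abort("x must satisfy 0 <= x <= n")
  a <- x + 1
  b <- n - x + 1
  if (method == "exact") {
    h <- beta_hdi(a, b, mass)
  } else {
    set.seed(seed)
    h <- hdi(rbeta(n_draws, a, b), mass)
  }
  tibble::tibble(species = species, x = as.integer(x), n = as.integer(n),
                 mean = a / (a + b),
                 hdi_lower = unname(h["lower"]), hdi_upper = unname(h["upper"]),
                 method = "bayes_laplace")
}

# shortest interval holding `mass` of a Beta(a, b); boundary-attached when
# the density is monotone (a <= 1 or b <= 1)
beta_hdi <- function(a, b, mass = 0.95) {
  if (a <= 1 && b <= 1) {          # flat or U-shaped: fall back to central
    return(c(lower = qbeta((1 - mass) / 2, a, b),
             upper = qbeta(1 - (1 - mass) / 2, a, b)))
  }
  if (a <= 1) return(c(lower = 0, upper = qbeta(mass, a, b)))
  if (b <= 1) return(c(lower = qbeta(1 - mass, a, b), upper = 1))
  width <- function(lo) {
    qbeta(pmin(pbeta(lo, a, b) + mass, 1), a, b) - lo
  }
  opt <- optimize(width, lower = 0, upper = qbeta(1 - mass, a, b),
                  tol = 1e-10)
  lo <- opt$minimum
  c(lower = lo, upper = qbeta(pbeta(lo, a, b) + mass, a, b))
}

#' Pool one species' records into total counts
#'
#' @param df `avm_tbl`.
#' @param species species name (normalised before matching).
#' @return named integer vector `c(x, n)`: total dead and total caught.
#' @export
pool_species_records <- function(df, species) {
  sp <- normalize_species(species)
  rows <- df[df$species == sp, , drop = FALSE]
  if (nrow(rows) == 0L) abort(paste0("species not in data: ", species))
  c(x = sum(rows$n_dead), n = sum(rows$n_caught))
}

#' Bayes-Laplace mortality table for data-poor species
#'
#' Species with fewer than `min_records` effect sizes are routed away from
#' the meta-regression and summarised instead by pooling their counts and
#' applying [bayes_laplace_estimate()].
#'
#' @param df `avm_tbl`.
#' @param min_records routing threshold (default 5): species with fewer
#'   records are estimated here.
#' @param species explicit species vector overriding the threshold routing.
#' @param mass HDI mass.
#' @return tibble, one row per sparse species.
#' @export
sparse_species_table <- function(df, min_records = 5, species = NULL,
                                 mass = 0.95) {
  if (is.null(species)) {
    counts <- table(df$species)
    species <- names(counts)[counts < min_records]
  } else {
    species <- normalize_species(species)
  }
  if (!length(species)) {
    return(bayes_laplace_estimate(0, 1)[0, ])
  }
  purrr::map_dfr(sort(species), function(sp) {
    xn <- pool_species_records(df, sp)
    bayes_laplace_estimate(xn["x"], xn["n"], mass = mass, species = sp)
  })
}
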