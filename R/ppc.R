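#' Posterior predictive check
#'
#' Draws `n_rep` replicated datasets from the posterior predictive
#' (binomial deaths at the fitted record-level probabilities) and compares
#' observed summaries with their replicated distributions: the record-level
#' death-proportion distribution and per-species death totals with central
#' 95% bands.
#'
#' @param fit `avm_fit`.
#' @param df dataset (defaults to the fit's data).
#' @param n_rep number of posterior predictive replicates (>= 1).
#' @param seed RNG seed for selecting posterior draws and binomial noise.
#' @return object of class `avm_ppc`: `rep_stats` (per-replicate mean/sd of
#'   record proportions), `observed_stats`, `species` (observed totals with
#'   replicated bands and an `inside` flag), `rep_props` (records x n_rep
#'   matrix of replicated proportions); [ggplot2::autoplot()] overlays the
#'   observed and replicated proportion densities.
#' @export
posterior_predictive_check <- function(fit, df = fit$data, n_rep = 200,
                                       seed = 1) {
  if (n_rep < 1) abort("n_rep must be >= 1")
  if (nrow(df) != ncol(fit$p)) abort("dataset does not match fit")
  set.seed(seed)
  N <- nrow(df)
  total <- nrow(fit$p)
  idx <- sample.int(total, n_rep, replace = n_rep > total)
  x_rep <- vapply(idx, function(s) rbinom(N, df$n_caught, fit$p[s, ]),
                  integer(N))
  prop_rep <- sweep(x_rep, 1, df$n_caught, "/")

  rep_stats <- tibble::tibble(
    rep = seq_len(n_rep),
    mean_prop = colMeans(prop_rep),
    sd_prop = apply(prop_rep, 2, sd),
    total_dead = colSums(x_rep)
  )
  observed <- tibble::tibble(
    mean_prop = mean(df$n_dead / df$n_caught),
    sd_prop = sd(df$n_dead / df$n_caught),
    total_dead = sum(df$n_dead)
  )
  sp_rep <- rowsum(x_rep, df$species)
  sp_obs <- rowsum(df$n_dead, df$species)[, 1]
  species <- tibble::tibble(
    species = rownames(sp_rep),
    observed = sp_obs[rownames(sp_rep)],
    rep_lower = apply(sp_rep, 1, quantile, 0.025),
    rep_upper = apply(sp_rep, 1, quantile, 0.975)
  )
  species$inside <- species$observed >= species$rep_lower &
    species$observed <= species$rep_upper

  structure(list(rep_stats = rep_stats, observed_stats = observed,
                 species = species, rep_props = prop_rep,
                 obs_props = df$n_dead / df$n_caught, n_rep = n_rep),
            class = "avm_ppc")
}

#' @method print avm_ppc
#' @export
print.avm_ppc <- function(x, ...) {
  cat("<avm_ppc> ", x$n_rep, " replicates\n", sep = "")
  cat(sprintf("  observed mean proportion %.3f; replicated central 95%%: [%.3f, %.3f]\n",
              x$observed_stats$mean_prop,
              quantile(x$rep_stats$mean_prop, 0.025),
              quantile(x$rep_stats$mean_prop, 0.975)))
  out <- sum(!x$species$inside)
  cat("  species outside replicated 95% band:", out, "of", nrow(x$species), "\n")
  invisible(x)
}

#' @rdname posterior_predictive_check
#' @param object `avm_ppc`.
#' @param n_overlay replicate densities to overlay.
#' @param ... ignored.
#' @export
autoplot.avm_ppc <- function(object, n_overlay = 50, ...) {
  keep <- seq_len(min(n_overlay, object$n_rep))
  rep_df <- tidyr::pivot_longer(
    tibble::as_tibble(object$rep_props[, keep, drop = FALSE],
                      .name_repair = ~ paste0("rep", keep)),
    dplyr::everything(), names_to = "rep", values_to = "prop")
  obs_df <- tibble::tibble(prop = object$obs_props)
  ggplot2::ggplot(rep_df, ggplot2::aes(x = .data$prop, group = .data$rep)) +
    ggplot2::geom_density(colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_density(data = obs_df, ggplot2::aes(group = NULL),
                          colour = "black", linewidth = 0.9) +
    ggplot2::labs(x = "record-level AVM proportion", y = "density",
                  title = "Posterior predictive check",
                  subtitle = "black = observed, grey = replicated") +
    ggplot2::theme_minimal()
}
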