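#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy posterior summary of a fitted meta-regression
#'
#' One row per core parameter (intercept, fixed effects, spline linear
#' terms, group-level sds): posterior mean, 95% HDI, probability of
#' direction, and convergence diagnostics.
#'
#' @param x `avm_fit`.
#' @param mass HDI mass.
#' @param ... ignored.
#' @return tibble: term, estimate, hdi bounds, pd, rhat, ess_bulk, ess_tail.
#' @export
tidy.avm_fit <- function(x, mass = 0.95, ...) {
  pars <- dimnames(x$draws)[[3]]
  pars <- pars[!grepl("^spl_", pars)]   # basis coefficients stay internal
  out <- purrr::map_dfr(pars, function(p) {
    d <- as.numeric(x$draws[, , p])
    h <- hdi(d, mass)
    tibble::tibble(term = p, estimate = mean(d),
                   hdi_lower = unname(h["lower"]),
                   hdi_upper = unname(h["upper"]),
                   pd = if (startsWith(p, "sigma")) NA_real_ else p_direction(d))
  })
  dplyr::left_join(out, x$diagnostics,
                   by = c(term = "parameter"))
}

#' One-line model fit summary
#'
#' @param x `avm_fit`.
#' @param ... ignored.
#' @return one-row tibble: records, species, draws, chains, converged,
#'   max rhat, elapsed seconds.
#' @export
glance.avm_fit <- function(x, ...) {
  d <- dim(x$draws)
  tibble::tibble(
    n_records = nrow(x$data),
    n_species = length(x$groups$species %||% character(0)),
    n_draws = d[1] * d[2],
    n_chains = d[2],
    converged = x$converged,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    elapsed = x$elapsed
  )
}

#' Parameter interval plot for a fitted meta-regression
#'
#' @param object `avm_fit`.
#' @param ... passed to [tidy.avm_fit()].
#' @export
autoplot.avm_fit <- function(object, ...) {
  td <- tidy(object, ...)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hdi_lower,
                                         xmax = .data$hdi_upper), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "posterior mean and 95% HDI (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Species-rate plot (posterior means and HDIs, ascending)
#'
#' @param fit `avm_fit` with species effects.
#' @param ... passed to [species_avm()].
#' @export
plot_species_avm <- function(fit, ...) {
  tab <- species_avm(fit, ...)
  tab$species <- factor(tab$species, levels = tab$species)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean, y = .data$species)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hdi_lower,
                                         xmax = .data$hdi_upper), height = 0,
                            colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "species-specific AVM rate (posterior mean, 95% HDI)",
                  y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
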