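#' Pooled at-vessel mortality rate
#'
#' Per posterior draw, the population-level expected mortality on the
#' response scale — the inverse-logit linear predictor with all group
#' effects at zero — averaged over the observed moderator configurations,
#' weighted proportionally to record sample size (`n_caught`) by default.
#'
#' @param fit `avm_fit`.
#' @param weights `"proportional"` (sample-size weights) or `"equal"`.
#' @param mass HDI mass.
#' @return one-row tibble (quantity, mean, hdi bounds, n_draws) with the
#'   draw vector in attribute `"draws"`.
#' @export
pooled_avm <- function(fit, weights = c("proportional", "equal"),
                       mass = 0.95) {
  weights <- match.arg(weights)
  w <- if (weights == "proportional") fit$data$n_caught else rep(1, nrow(fit$data))
  eta <- predict_eta_pop(fit, fit$data)
  draws <- as.numeric(plogis(eta) %*% (w / sum(w)))
  out <- posterior_summary(draws, "pooled_avm", mass, signed = FALSE)
  attr(out, "draws") <- draws
  out
}

#' Species-specific at-vessel mortality rates
#'
#' Per species and draw, inverse-logit of the population-level predictor
#' plus that species' phylogenetic effect, averaged over the observed
#' moderator configurations; summaries sorted ascending by posterior mean
#' (ties by name).
#'
#' @inheritParams pooled_avm
#' @param species optional subset of species names.
#' @return tibble, one row per species, sorted by mean; draw matrix
#'   (draws x species) in attribute `"draws"`.
#' @export
species_avm <- function(fit, species = NULL,
                        weights = c("proportional", "equal"), mass = 0.95) {
  weights <- match.arg(weights)
  if (is.null(fit$u_species)) abort("fit has no species-level effects")
  sp_all <- colnames(fit$u_species)
  species <- if (is.null(species)) sp_all else normalize_species(species)
  miss <- setdiff(species, sp_all)
  if (length(miss)) abort(paste0("species not in fit: ",
                                 paste(miss, collapse = ", ")))
  w <- if (weights == "proportional") fit$data$n_caught else rep(1, nrow(fit$data))
  w <- w / sum(w)
  eta <- predict_eta_pop(fit, fit$data)
  dm <- vapply(species, function(s) {
    as.numeric(plogis(eta + fit$u_species[, s]) %*% w)
  }, numeric(nrow(eta)))
  out <- purrr::map_dfr(species, function(s) {
    dplyr::mutate(posterior_summary(dm[, s], s, mass, signed = FALSE),
                  species = s, .before = 1)
  })
  out <- dplyr::arrange(out, .data$mean, .data$species)
  attr(out, "draws") <- dm
  out[, c("species", "mean", "hdi_lower", "hdi_upper", "n_draws")]
}

#' Phylogenetic signal
#'
#' Posterior proportion of the summed group-level variances attributable to
#' the phylogenetic species component:
#' `lambda = sigma_phylo^2 / (sigma_phylo^2 + sum of other group variances)`,
#' computed per draw; every draw lies in `[0, 1]`.
#'
#' @param fit `avm_fit` with a phylogenetic term and at least one other
#'   group-level sd.
#' @param mass HDI mass.
#' @return one-row tibble (mean, hdi bounds, n_draws); lambda draws in
#'   attribute `"draws"`.
#' @export
phylo_signal <- function(fit, mass = 0.95) {
  pars <- dimnames(fit$draws)[[3]]
  if (!"sigma_phylo" %in% pars) abort("fit has no phylogenetic term")
  others <- intersect(c("sigma_study", "sigma_record", "sigma_group"), pars)
  if (!length(others)) abort("need at least one non-phylogenetic group sd")
  s2 <- flat_draws(fit, c("sigma_phylo", others))^2
  draws <- s2[, "sigma_phylo"] / rowSums(s2)
  out <- posterior_summary(draws, "phylo_signal", mass, signed = FALSE)
  attr(out, "draws") <- draws
  out
}

#' Estimated marginal means of a moderator
#'
#' Model-predicted mortality for each level of `by`, averaged over the
#' reference grid of the remaining moderators observed in the data, with
#' grid weights proportional to sample size (`n_caught` totals) or equal
#' across distinct configurations.
#'
#' @param fit `avm_fit`.
#' @param by a categorical moderator present in the fit's fixed effects.
#' @param weights `"proportional"` or `"equal"` grid weights.
#' @param mass HDI mass.
#' @return tibble, one row per level; draw matrix in attribute `"draws"`.
#' @export
marginal_means <- function(fit, by, weights = c("proportional", "equal"),
                           mass = 0.95) {
  weights <- match.arg(weights)
  if (!by %in% names(fit$design$xlevels)) {
    abort(paste0("term not in model fixed effects: ", by))
  }
  levels_by <- fit$design$xlevels[[by]]
  other <- c(setdiff(names(fit$design$xlevels), by),
             vapply(fit$design$splines, `[[`, character(1), "var"))
  dat <- tibble::as_tibble(fit$data)
  if (length(other)) {
    grid <- dplyr::summarise(dplyr::group_by(dat, dplyr::across(dplyr::all_of(other))),
                             .w = sum(.data$n_caught), .groups = "drop")
    if (weights == "equal") grid$.w <- 1
  } else {
    grid <- tibble::tibble(.w = 1)
  }
  w <- grid$.w / sum(grid$.w)
  dm <- vapply(levels_by, function(l) {
    nd <- grid
    nd[[by]] <- l
    as.numeric(plogis(predict_eta_pop(fit, nd)) %*% w)
  }, numeric(n_draws_total(fit)))
  out <- purrr::map_dfr(levels_by, function(l) {
    dplyr::mutate(posterior_summary(dm[, l], paste0(by, ":", l), mass,
                                    signed = FALSE),
                  level = l, .before = 1)
  })
  attr(out, "draws") <- dm
  attr(out, "by") <- by
  out
}

#' Posterior ratio of marginal mortality between two moderator levels
#'
#' Per draw, the ratio of the marginal mean mortality at `level_a` over
#' `level_b` — e.g. how many times more likely a capture is to be dead at
#' haulback in one ocean basin than another.
#'
#' @param fit `avm_fit`.
#' @param term categorical moderator.
#' @param level_a,level_b levels of `term` (numerator, denominator).
#' @param weights,mass passed to [marginal_means()].
#' @return one-row tibble: mean, HDI bounds, `prob_gt_1` (posterior
#'   probability the ratio exceeds 1); draws in attribute `"draws"`.
#' @export
ratio_contrast <- function(fit, term, level_a, level_b,
                           weights = "proportional", mass = 0.95) {
  if (identical(level_a, level_b)) {
    draws <- rep(1, n_draws_total(fit))
  } else {
    mm <- marginal_means(fit, term, weights = weights, mass = mass)
    dm <- attr(mm, "draws")
    for (l in c(level_a, level_b)) {
      if (!l %in% colnames(dm)) abort(paste0("no such level of ", term, ": ", l))
    }
    draws <- dm[, level_a] / dm[, level_b]
  }
  h <- hdi(draws, mass)
  out <- tibble::tibble(
    quantity = paste0(term, ": ", level_a, " / ", level_b),
    mean = mean(draws),
    hdi_lower = unname(h["lower"]), hdi_upper = unname(h["upper"]),
    prob_gt_1 = mean(draws > 1),
    n_draws = length(draws)
  )
  attr(out, "draws") <- draws
  out
}
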