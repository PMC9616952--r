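#' Screen candidate moderators with a weighted random forest
#'
#' Ranks candidate predictors of at-vessel mortality by permutation
#' importance from random forests fit to the continuity-corrected logit
#' proportion, weighting records by random-effects meta-analytic weights
#' `1 / (v_i + tau^2)` (delta-method logit variance plus a
#' DerSimonian-Laird between-study variance) and bootstrapping whole
#' studies (clustered bootstrap) to respect within-study dependence.
#' Importance is the mean permutation importance across replicates,
#' rescaled so the top predictor scores 100; predictors above `threshold`
#' percent are flagged informative.
#'
#' Taxonomic predictors (genus/family/order) may rank highly; they are
#' screened but excluded from downstream fixed effects by
#' [screened_moderators()], since the meta-regression models that structure
#' through the phylogenetic tree instead.
#'
#' @param df complete (imputed) `avm_tbl`.
#' @param candidates candidate predictor columns; defaults to the gear /
#'   environment moderators plus genus, family and order.
#' @param n_boot clustered bootstrap replicates (>= 1).
#' @param threshold informativeness cut-off, percent of the maximum
#'   importance.
#' @param num_trees,min_node_size random-forest hyperparameters
#'   (`mtry = ceiling(sqrt(p))`).
#' @param seed RNG seed; results are identical across runs for a fixed
#'   seed.
#' @return tibble of class `avm_importance`: predictor, importance (percent
#'   of max), informative flag; attributes `threshold`, `n_boot`,
#'   `raw_importance`.
#' @export
screen_predictors <- function(df, candidates = NULL, n_boot = 100,
                              threshold = 10, num_trees = 500,
                              min_node_size = 5, seed = 1) {
  if (is.null(candidates)) {
    candidates <- c("genus", "family", "order", avm_moderators())
  }
  candidates <- intersect(candidates, names(df))
  if (length(candidates) < 2L) abort("need at least 2 candidate predictors")
  if (threshold <= 0) abort("threshold must be > 0")
  for (v in candidates) {
    if (anyNA(df[[v]])) {
      abort(paste0("candidate '", v, "' has missing values; impute first ",
                   "or restrict candidates to complete columns"))
    }
  }
  clusters <- unique(df$study_id)
  if (length(clusters) < 2L) abort("clustered bootstrap needs >= 2 studies")

  yi <- logit_cc(df$n_dead, df$n_caught)
  if (sd(yi) < 1e-12) abort("constant response: all records have the same rate")
  vi <- var_logit_cc(df$n_dead, df$n_caught)
  tau2 <- dl_tau2(yi, vi)
  w <- 1 / (vi + tau2)

  dat <- tibble::as_tibble(df)[, candidates]
  for (v in candidates) if (!is.numeric(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  dat$.y <- yi

  seeds <- draw_seeds(seed, 2L * n_boot)
  imp <- matrix(0, n_boot, length(candidates),
                dimnames = list(NULL, candidates))
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    take <- sample(clusters, length(clusters), replace = TRUE)
    rows <- unlist(lapply(take, function(cl) which(df$study_id == cl)),
                   use.names = FALSE)
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = dat[rows, ],
      case.weights = w[rows], importance = "permutation",
      num.trees = num_trees, mtry = ceiling(sqrt(length(candidates))),
      min.node.size = min_node_size, seed = seeds[n_boot + b],
      num.threads = 1, verbose = FALSE)
    imp[b, names(rf$variable.importance)] <- rf$variable.importance
  }
  raw <- colMeans(imp)
  scaled <- 100 * raw / max(raw)
  out <- tibble::tibble(
    predictor = candidates,
    importance = unname(scaled[candidates]),
    informative = unname(scaled[candidates]) > threshold
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  class(out) <- c("avm_importance", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "n_boot") <- n_boot
  attr(out, "raw_importance") <- raw
  out
}

#' Informative non-taxonomic moderators from a screening table
#'
#' Applies the substitution rule: predictors over the threshold, minus
#' genus/family/order (handled by the phylogenetic term), plus any
#' `always_keep` moderators of operational interest.
#'
#' @param importance `avm_importance` from [screen_predictors()].
#' @param always_keep moderators retained regardless of importance.
#' @return character vector of moderator names for the model fixed effects.
#' @export
screened_moderators <- function(importance,
                                always_keep = character(0)) {
  keep <- importance$predictor[importance$informative]
  keep <- setdiff(keep, c("genus", "family", "order", "species"))
  union(keep, always_keep)
}

#' @rdname screen_predictors
#' @param object `avm_importance`.
#' @param ... ignored.
#' @export
autoplot.avm_importance <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      predictor = stats::reorder(.data$predictor,
                                                 .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$predictor,
                                   fill = .data$informative)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"), guide = "none") +
    ggplot2::labs(x = "permutation importance (% of maximum)", y = NULL) +
    ggplot2::theme_minimal()
}
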