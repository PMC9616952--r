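#' Impute missing moderators by chained random forests
#'
#' Iterative column-wise random-forest imputation: each incomplete column
#' is regressed on the other predictors (with current imputations filled
#' in) and its missing cells re-predicted, cycling until the summed
#' out-of-bag error stops improving or `max_iter` is reached. Numeric
#' imputations use predictive mean matching — a value is drawn from the
#' `pmm_donors` observed records whose predictions are nearest, so no value
#' absent from the observed data is ever imputed. Categorical imputations
#' take the forest's class vote. Observed cells are never altered.
#'
#' @param df `avm_tbl`, possibly with `NA` in numeric moderators.
#' @param max_iter maximum chaining iterations.
#' @param pmm_donors donor pool size for predictive mean matching.
#' @param num_trees trees per forest.
#' @param seed RNG seed.
#' @param predictors columns used as features (defaults to taxonomy plus
#'   all moderators).
#' @return `avm_imputed` (an `avm_tbl` with no missing moderator cells);
#'   attributes: `imputed_cells` (logical matrix over the target columns),
#'   `oob_trace` (per-iteration mean out-of-bag error).
#' @export
impute_missing <- function(df, max_iter = 10, pmm_donors = 5,
                           num_trees = 500, seed = 1, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- intersect(c("genus", "family", "order", avm_moderators()),
                            names(df))
  }
  targets <- predictors[vapply(predictors, function(v) anyNA(df[[v]]),
                               logical(1))]
  flags <- vapply(targets, function(v) is.na(df[[v]]), logical(nrow(df)))
  flags <- matrix(flags, nrow = nrow(df),
                  dimnames = list(NULL, targets))
  if (!length(targets)) {
    out <- df
    class(out) <- unique(c("avm_imputed", class(df)))
    attr(out, "imputed_cells") <- flags
    attr(out, "oob_trace") <- numeric(0)
    return(out)
  }
  for (v in targets) {
    if (all(is.na(df[[v]]))) abort(paste0("column entirely missing: ", v))
    if (mean(is.na(df[[v]])) >= 0.5) {
      abort(paste0("column '", v, "' is >= 50% missing; imputation refused"))
    }
  }
  if (!length(setdiff(predictors, targets))) {
    abort("no complete predictor available to seed the chaining")
  }

  work <- tibble::as_tibble(df)[, predictors]
  for (v in predictors) if (!is.numeric(work[[v]])) work[[v]] <- factor(work[[v]])

  # deterministic starting fill: median / modal class
  for (v in targets) {
    obs <- work[[v]][!flags[, v]]
    fill <- if (is.numeric(obs)) median(obs) else names(which.max(table(obs)))
    work[[v]][flags[, v]] <- fill
  }
  # order by increasing missingness so better-observed columns chain first
  targets <- targets[order(colSums(flags[, targets, drop = FALSE]))]

  seeds <- draw_seeds(seed, max_iter * length(targets) * 2L)
  s_i <- 0L
  oob_trace <- numeric(0)
  best <- Inf
  snapshot <- work
  for (it in seq_len(max_iter)) {
    oob <- numeric(0)
    for (v in targets) {
      s_i <- s_i + 1L
      miss <- flags[, v]
      obs_vals <- work[[v]][!miss]
      if (length(unique(obs_vals)) == 1L) {       # constant column: forced value
        work[[v]][miss] <- obs_vals[1]
        oob <- c(oob, 0)
        next
      }
      feat <- setdiff(predictors, v)
      dtrain <- work[!miss, c(v, feat)]
      rf <- ranger::ranger(
        dependent.variable.name = v, data = dtrain,
        num.trees = num_trees, min.node.size = 5,
        seed = seeds[s_i], num.threads = 1, verbose = FALSE,
        respect.unordered.factors = "order")
      pred <- predict(rf, work[miss, feat, drop = FALSE],
                      num.threads = 1)$predictions
      if (is.numeric(work[[v]])) {
        # predictive mean matching against observed-cell predictions
        pred_obs <- rf$predictions            # out-of-bag predictions
        if (anyNA(pred_obs)) {
          pred_obs[is.na(pred_obs)] <- predict(
            rf, dtrain[is.na(pred_obs), feat, drop = FALSE],
            num.threads = 1)$predictions
        }
        set.seed(seeds[s_i + max_iter * length(targets)])
        work[[v]][miss] <- vapply(pred, function(p) {
          d <- abs(pred_obs - p)
          donors <- order(d)[seq_len(min(pmm_donors, length(d)))]
          obs_vals[sample(donors, 1L)]
        }, numeric(1))
        oob <- c(oob, rf$prediction.error / max(var(obs_vals), 1e-12))
      } else {
        work[[v]][miss] <- pred
        oob <- c(oob, rf$prediction.error)
      }
    }
    oob_trace <- c(oob_trace, mean(oob))
    if (mean(oob) < best - 1e-6) {
      best <- mean(oob)
      snapshot <- work
    } else {
      work <- snapshot
      break
    }
  }

  out <- df
  for (v in targets) {
    vals <- if (is.factor(work[[v]])) as.character(work[[v]]) else work[[v]]
    out[[v]][flags[, v]] <- vals[flags[, v]]
  }
  class(out) <- unique(c("avm_imputed", class(df)))
  attr(out, "imputed_cells") <- flags
  attr(out, "oob_trace") <- oob_trace
  attr(out, "load_report") <- attr(df, "load_report")
  out
}
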