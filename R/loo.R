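# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO) and Bayesian stacking, computed from a draws x observations
# pointwise log-likelihood matrix.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# generalized Pareto fit to exceedances via the Zhang-Stephens
# profile-posterior method, with the weak shape prior used in PSIS
gpd_fit <- function(x, prior = 10, min_grid = 30) {
  x <- sort(x)
  N <- length(x)
  if (N < 5 || x[N] <= 0) return(c(k = NA_real_, sigma = NA_real_))
  M <- min_grid + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  bs <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- N * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  k <- mean(log1p(-b * x))
  sigma <- -k / b
  k <- (k * N + prior * 0.5) / (N + prior)   # shape shrunk toward 0.5
  c(k = k, sigma = sigma)
}

qgpd <- function(p, mu, k, sigma) {
  if (abs(k) < 1e-12) return(mu - sigma * log1p(-p))
  mu + sigma * expm1(-k * log1p(-p)) / k
}

# smooth one vector of raw log importance ratios; returns normalized log
# weights and the Pareto shape estimate
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  if (M >= 5) {
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1):S]
    cut <- exp(lr[ord[S - M]])
    exc <- exp(lr[tail_ids]) - cut
    fit <- gpd_fit(exc)
    khat <- unname(fit["k"])
    if (is.finite(khat)) {
      p <- (seq_len(M) - 0.5) / M
      q <- vapply(p, qgpd, numeric(1), mu = cut, k = fit["k"],
                  sigma = fit["sigma"])
      smoothed <- log(pmin(q, exp(max(lr))))
      lr[tail_ids[order(exp(lr[tail_ids]))]] <- sort(smoothed)
    }
  }
  list(log_weights = lr - log_sum_exp(lr), khat = khat)
}

#' PSIS leave-one-out cross-validation
#'
#' Approximate leave-one-out expected log predictive density from posterior
#' draws, using Pareto-smoothed importance sampling: per observation, the
#' importance ratios `1 / p(y_i | theta_s)` have their upper tail replaced
#' by expected order statistics of a generalized Pareto fit; the Pareto
#' shape `k` diagnoses reliability (values above 0.7 are flagged).
#'
#' @param log_lik draws x observations pointwise log-likelihood matrix, or
#'   an `avm_fit` (its stored `log_lik` is used).
#' @return object of class `avm_loo`: `elpd`, `se`, `p_loo`, and a
#'   `pointwise` tibble with per-observation `elpd_i`, `lpd_i`, `pareto_k`.
#' @export
psis_loo <- function(log_lik) {
  if (inherits(log_lik, "avm_fit")) log_lik <- log_lik$log_lik
  ll <- as.matrix(log_lik)
  S <- nrow(ll); N <- ncol(ll)
  if (S < 20) abort("need at least 20 draws for PSIS-LOO")
  out <- purrr::map_dfr(seq_len(N), function(i) {
    sm <- psis_smooth(-ll[, i])
    tibble::tibble(
      obs = i,
      elpd_i = log_sum_exp(sm$log_weights + ll[, i]),
      lpd_i = log_sum_exp(ll[, i]) - log(S),
      pareto_k = sm$khat
    )
  })
  structure(list(
    elpd = sum(out$elpd_i),
    se = sqrt(N * var(out$elpd_i)),
    p_loo = sum(out$lpd_i - out$elpd_i),
    pointwise = out,
    n_obs = N, n_draws = S
  ), class = "avm_loo")
}

#' @method print avm_loo
#' @export
print.avm_loo <- function(x, ...) {
  cat(sprintf("<avm_loo> elpd %.1f (SE %.1f), p_loo %.1f, %d obs, %d draws\n",
              x$elpd, x$se, x$p_loo, x$n_obs, x$n_draws))
  kbad <- sum(x$pointwise$pareto_k > 0.7, na.rm = TRUE)
  if (kbad) cat("  ", kbad, "observation(s) with Pareto k > 0.7\n")
  invisible(x)
}

# stacking weights: maximize the LOO log score over the simplex via a
# softmax parametrization
stacking_weights <- function(elpd_mat) {
  K <- ncol(elpd_mat)
  if (K == 1L) return(1)
  # center rows for numerical stability; row-wise constants do not change
  # the argmax
  elpd_mat <- elpd_mat - apply(elpd_mat, 1, max)
  obj <- function(a) {
    w <- exp(c(a, 0)); w <- w / sum(w)
    -sum(log(pmax(exp(elpd_mat) %*% w, 1e-300)))
  }
  opt <- optim(rep(0, K - 1), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  w <- exp(c(opt$par, 0))
  w / sum(w)
}

#' Compare fitted models by PSIS-LOO and Bayesian stacking
#'
#' @param ... `avm_fit` objects (or pointwise log-likelihood matrices),
#'   optionally named; all must share the same observation set.
#' @return tibble sorted by elpd: model, elpd, se, p_loo, elpd_diff and
#'   se_diff versus the best model, max Pareto k, stacking weight.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "avm_fit") &&
      !is.matrix(fits[[1]])) {
    fits <- fits[[1]]
  }
  nm <- names(fits) %||% rep("", length(fits))
  nm[!nzchar(nm)] <- paste0("model", which(!nzchar(nm)))
  lls <- lapply(fits, function(f) if (inherits(f, "avm_fit")) f$log_lik else as.matrix(f))
  nobs <- vapply(lls, ncol, integer(1))
  if (length(unique(nobs)) != 1L) abort("models have mismatched observation sets")
  loos <- lapply(lls, psis_loo)
  elpd_mat <- do.call(cbind, lapply(loos, function(l) l$pointwise$elpd_i))
  w <- stacking_weights(elpd_mat)
  best <- which.max(vapply(loos, `[[`, numeric(1), "elpd"))
  out <- purrr::map_dfr(seq_along(loos), function(k) {
    d <- elpd_mat[, k] - elpd_mat[, best]
    tibble::tibble(
      model = nm[k],
      elpd = loos[[k]]$elpd, se = loos[[k]]$se, p_loo = loos[[k]]$p_loo,
      elpd_diff = sum(d),
      se_diff = unname(sqrt(nobs[1] * var(d))),
      max_pareto_k = suppressWarnings(max(loos[[k]]$pointwise$pareto_k, na.rm = TRUE)),
      stacking_weight = w[k]
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$elpd))
}
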