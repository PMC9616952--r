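# Rank-normalized split-Rhat and bulk/tail effective sample size for
# iterations x chains draw matrices. Definitions follow the modern
# rank-based formulation: chains are split in half, draws are replaced by
# normal scores of their pooled ranks, and Rhat is the larger of the
# location (rank-normalized) and scale (folded rank-normalized) statistics.

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  if (half < 2L) abort("need at least 4 iterations per chain to split")
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(mat) {
  r <- rank(as.numeric(mat), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(mat), ncol = ncol(mat))
}

rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  chain_mean <- colMeans(mat)
  chain_var <- apply(mat, 2, var)
  W <- mean(chain_var)
  B <- n * var(chain_mean)
  if (!is.finite(W) || W < .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split-Rhat
#'
#' @param mat iterations x chains matrix of draws for one parameter.
#' @return scalar Rhat (NA for constant draws).
#' @export
rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) abort("Rhat requires at least 2 chains")
  s <- split_chains(mat)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - median(s))))
  max(bulk, folded)
}

# effective sample size of a (possibly transformed) draws matrix via
# per-chain autocovariances combined with Geyer's initial monotone sequence
ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  acov <- apply(mat, 2, function(x) {
    a <- acf(x, lag.max = n - 1, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  acov <- matrix(acov, nrow = n)
  chain_mean <- colMeans(mat)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + var(chain_mean)
  if (!is.finite(var_plus) || var_plus < .Machine$double.eps) return(NA_real_)

  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus   # rho[1] = lag 0
  max_t <- 1L
  t <- 1L
  rho_even <- 1
  rho_odd <- 0
  # Geyer initial positive sequence over paired sums
  P <- numeric(0)
  tt <- 2L
  while (tt + 1L <= n) {
    pair <- rho[tt] + rho[tt + 1L]
    if (!is.finite(pair) || pair <= 0) break
    P <- c(P, pair)
    tt <- tt + 2L
  }
  # initial monotone sequence
  if (length(P) > 1) P <- cummin(P)
  tau <- -1 + 2 * 1 + 2 * sum(P)   # lag-0 term contributes 1 (paired with itself)
  tau <- max(tau, 1 / log10(n * m + 10))
  ess <- n * m / tau
  min(ess, n * m * log10(n * m))
}

#' Bulk effective sample size (rank-normalized, split chains)
#' @param mat iterations x chains matrix.
#' @export
ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  ess_basic(rank_normalize(split_chains(mat)))
}

#' Tail effective sample size (minimum of the 5% and 95% quantile ESS)
#' @param mat iterations x chains matrix.
#' @export
ess_tail <- function(mat) {
  mat <- as.matrix(mat)
  s <- split_chains(mat)
  ind_ess <- vapply(c(0.05, 0.95), function(q) {
    ess_basic(0 + (s <= quantile(mat, q)))
  }, numeric(1))
  min(ind_ess, na.rm = TRUE)
}

#' Convergence diagnostics for a fitted model (or draws array)
#'
#' Per-parameter rank-normalized split-Rhat and bulk/tail ESS, and an
#' overall pass flag (`all(Rhat < 1.01)`), the convergence criterion used
#' throughout the pipeline.
#'
#' @param fit `avm_fit`, or a 3-d draws array `[iteration, chain, parameter]`.
#' @param pars optional parameter-name subset.
#' @return tibble: parameter, rhat, ess_bulk, ess_tail, plus attributes
#'   `pass` (logical) and `n_divergent` (always `NA` for the Gibbs backend,
#'   which has no divergence concept).
#' @export
convergence_report <- function(fit, pars = NULL) {
  draws <- if (inherits(fit, "avm_fit")) fit$draws else fit
  if (length(dim(draws)) != 3L) abort("expected [iteration, chain, parameter] array")
  if (dim(draws)[2] < 2L) abort("Rhat requires at least 2 chains")
  params <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  if (!is.null(pars)) params <- intersect(params, pars)
  out <- purrr::map_dfr(params, function(p) {
    m <- draws[, , p]
    tibble::tibble(parameter = p, rhat = rhat(m),
                   ess_bulk = ess_bulk(m), ess_tail = ess_tail(m))
  })
  attr(out, "pass") <- all(out$rhat < 1.01, na.rm = TRUE)
  attr(out, "n_divergent") <- NA_integer_
  out
}
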