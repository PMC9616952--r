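#' Highest density interval of posterior draws
#'
#' The shortest contiguous interval containing `mass` of the draws: among
#' all windows of `ceiling(mass * n)` consecutive sorted draws the narrowest
#' is returned (ties broken by the lower window). Never wider than the
#' equal-tailed interval of the same mass.
#'
#' @param draws numeric sample vector.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2L) abort("need at least 2 finite draws")
  if (mass <= 0 || mass >= 1) abort("mass must be in (0, 1)")
  s <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  k <- n - m + 1L
  widths <- s[m:n] - s[1:k]
  i <- which.min(widths)                  # which.min takes the first tie
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Probability of direction
#'
#' Posterior probability that the quantity carries its majority sign:
#' `max(P(x > 0), P(x < 0))`, with draws exactly at zero split equally
#' between the signs. Always in `[0.5, 1]`.
#'
#' @param draws numeric sample vector.
#' @return scalar in `[0.5, 1]`.
#' @export
p_direction <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (!length(draws)) abort("no finite draws")
  frac_pos <- mean(draws > 0) + 0.5 * mean(draws == 0)
  max(frac_pos, 1 - frac_pos)
}

# one-row tibble summary of a derived posterior quantity
posterior_summary <- function(draws, quantity, mass = 0.95, signed = TRUE) {
  h <- hdi(draws, mass)
  tibble::tibble(
    quantity = quantity,
    mean = mean(draws),
    hdi_lower = unname(h["lower"]),
    hdi_upper = unname(h["upper"]),
    pd = if (signed) p_direction(draws) else NA_real_,
    n_draws = length(draws)
  )
}

# equal-tailed interval, used as comparison in tests and plots
eti <- function(draws, mass = 0.95) {
  a <- (1 - mass) / 2
  q <- unname(quantile(draws, c(a, 1 - a), names = FALSE, type = 7))
  c(lower = q[1], upper = q[2])
}
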