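#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats plogis qlogis rnorm rbinom runif quantile setNames
#' @importFrom stats median sd var dbinom qbeta pbeta dbeta rbeta optimize
#' @importFrom stats model.matrix complete.cases weighted.mean predict acf
#' @importFrom stats qnorm pnorm rnbinom qgamma optim rlnorm aggregate
#' @importFrom utils head tail
NULL

# logit with explicit continuity correction for x in {0, n}
logit_cc <- function(x, n) {
  p <- (x + 0.5) / (n + 1)
  qlogis(p)
}

# delta-method variance of the continuity-corrected logit proportion
var_logit_cc <- function(x, n) {
  1 / (x + 0.5) + 1 / (n - x + 0.5)
}

inv_logit <- stats::plogis

`%na%` <- function(a, b) ifelse(is.na(a), b, a)

# collapse repeated whitespace, trim, and sentence-case the genus part of
# a binomial name so data species labels match tree tip labels
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x <- gsub("_", " ", x)
  parts <- strsplit(x, " ", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 0L || !nzchar(p[1])) return(NA_character_)
    p[1] <- paste0(toupper(substr(p[1], 1, 1)), tolower(substr(p[1], 2, nchar(p[1]))))
    if (length(p) > 1L) p[-1] <- tolower(p[-1])
    paste(p, collapse = " ")
  }, character(1))
}

# species labels as they appear on tree tips (underscored)
species_to_tip <- function(x) gsub(" ", "_", normalize_species(x))

draw_seeds <- function(seed, n) {
  # derive per-stage/per-replicate seeds from one root seed, keeping them
  # within the 32-bit integer range
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
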