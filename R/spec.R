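#' Weakly informative prior settings for the meta-regression
#'
#' Defaults: Student-t(3, 0, 2.5) on the logit-scale intercept, Normal(0, 2)
#' on fixed-effect coefficients, half-Student-t(3, 0, 2.5) on every
#' group-level and spline standard deviation. These are the common weakly
#' informative defaults for binomial multilevel meta-analysis: they keep
#' plausible mortality rates essentially unconstrained on (0, 1) while
#' regularising extreme logits.
#'
#' @param intercept_df,intercept_scale Student-t prior on the intercept.
#' @param beta_sd Normal sd for fixed-effect coefficients.
#' @param sd_df,sd_scale half-Student-t prior on standard deviations.
#' @return list of prior settings.
#' @export
avm_priors <- function(intercept_df = 3, intercept_scale = 2.5,
                       beta_sd = 2, sd_df = 3, sd_scale = 2.5) {
  list(intercept_df = intercept_df, intercept_scale = intercept_scale,
       beta_sd = beta_sd, sd_df = sd_df, sd_scale = sd_scale)
}

#' Sampler settings
#'
#' Two profiles: `"paper"` runs 4 chains of 10,000 post-warmup iterations
#' after 2,000 warmup (the full-analysis configuration); `"ci"` runs 4
#' chains of 500 post-warmup iterations after 500 warmup, sized for test
#' suites and quick exploration.
#'
#' @param profile `"ci"` or `"paper"`; sets defaults for the other
#'   arguments, each individually overridable.
#' @param chains number of chains (>= 2).
#' @param iter post-warmup iterations per chain.
#' @param warmup warmup (burn-in) iterations discarded per chain.
#' @param adapt sampler adaptation iterations before warmup.
#' @param seed integer seed; chain RNGs derive from it deterministically.
#' @return list of sampler settings.
#' @export
avm_sampler <- function(profile = c("ci", "paper"), chains = 4,
                        iter = NULL, warmup = NULL, adapt = NULL, seed = 1) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") c(iter = 10000, warmup = 2000, adapt = 1000)
         else c(iter = 500, warmup = 500, adapt = 500)
  list(profile = profile, chains = as.integer(chains),
       iter = as.integer(iter %||% def["iter"]),
       warmup = as.integer(warmup %||% def["warmup"]),
       adapt = as.integer(adapt %||% def["adapt"]),
       seed = as.integer(seed))
}

#' Declarative specification of a binomial-Normal meta-regression
#'
#' Describes the model `logit(p_i) = intercept + fixed effects + spline
#' smooths + group effects` with binomial likelihood
#' `n_dead_i ~ Binomial(n_caught_i, p_i)`. Categorical moderators use
#' treatment contrasts with the alphabetically first level as reference;
#' `"unknown"` levels enter as ordinary category levels. The species-level
#' effect, when present, is multivariate Normal with Brownian correlation
#' from the phylogeny (`phylo = TRUE`) or any supplied correlation matrix;
#' study, record-within-study and research-group effects are independent
#' Normals. Continuous covariates in `spline` get a penalized cubic
#' B-spline smooth (`spline_k` basis functions, second-difference penalty)
#' in its mixed-model representation: an unpenalised linear part plus
#' independent Normal basis coefficients with their own sd.
#'
#' @param fixed character vector of categorical moderators, e.g.
#'   `c("ocean", "hook_shape")`.
#' @param interactions character vector of two-way interactions written
#'   `"a:b"`.
#' @param spline character vector of continuous covariates to smooth
#'   (possibly empty).
#' @param spline_k basis dimension per smooth.
#' @param phylo logical: include the phylogenetically correlated
#'   species-level effect (requires a tree or correlation matrix at fit
#'   time). `FALSE` for single-species or species-specific models.
#' @param group subset of `c("study", "record", "research_group")`.
#' @param priors from [avm_priors()].
#' @param sampler from [avm_sampler()].
#' @return list of class `avm_model_spec`.
#' @export
avm_model_spec <- function(fixed = "ocean", interactions = character(0),
                           spline = "hooks_between_floats", spline_k = 10,
                           phylo = TRUE,
                           group = c("study", "record", "research_group"),
                           priors = avm_priors(), sampler = avm_sampler()) {
  group <- if (length(group)) match.arg(group, several.ok = TRUE)
           else character(0)
  if (sampler$chains < 2L) abort("at least 2 chains are required")
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% fixed)) {
      abort(paste0("interaction terms must combine two fixed moderators: ", ia))
    }
  }
  structure(list(
    fixed = unique(fixed %||% character(0)),
    interactions = interactions,
    spline = unique(spline %||% character(0)),
    spline_k = as.integer(spline_k),
    phylo = isTRUE(phylo),
    group = group,
    priors = priors,
    sampler = sampler
  ), class = "avm_model_spec")
}

#' @method print avm_model_spec
#' @export
print.avm_model_spec <- function(x, ...) {
  cat("<avm_model_spec>\n")
  cat("  fixed:", if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "(intercept only)", "\n")
  if (length(x$interactions)) cat("  interactions:", paste(x$interactions, collapse = ", "), "\n")
  if (length(x$spline)) cat("  splines:", paste0("s(", x$spline, ", k=", x$spline_k, ")", collapse = ", "), "\n")
  cat("  species effect:", if (x$phylo) "phylogenetic (Brownian C)" else "none", "\n")
  cat("  groups:", paste(x$group, collapse = ", "), "\n")
  cat(sprintf("  sampler: %d chains x %d iter (+%d warmup), profile %s, seed %d\n",
              x$sampler$chains, x$sampler$iter, x$sampler$warmup,
              x$sampler$profile, x$sampler$seed))
  invisible(x)
}

#' Serialize / restore a model spec
#'
#' @param spec `avm_model_spec`.
#' @param path JSON file path.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$interactions <- as.character(x$interactions %||% character(0))
  x$spline <- as.character(x$spline %||% character(0))
  do.call(avm_model_spec, c(
    x[c("fixed", "interactions", "spline", "spline_k", "phylo", "group")],
    list(priors = do.call(avm_priors, as.list(x$priors)),
         sampler = do.call(avm_sampler, as.list(
           x$sampler[c("profile", "chains", "iter", "warmup", "adapt", "seed")])))
  ))
}
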