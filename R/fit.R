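#' Fit the Bayesian binomial-Normal hierarchical meta-regression
#'
#' Fits `n_dead_i ~ Binomial(n_caught_i, p_i)` with
#' `logit(p_i) = intercept + X beta + spline smooths + group effects` by
#' MCMC (JAGS backend; Gibbs/slice updates). Species-level effects are
#' multivariate Normal, `u ~ MVN(0, sigma_phylo^2 C)` with `C` the Brownian
#' correlation from the phylogeny (sampled non-centrally through the
#' Cholesky factor of `C` plus a 1e-8 diagonal jitter); study,
#' record-within-study and research-group effects are independent Normals
#' with half-Student-t sd priors. Chain RNG seeds derive deterministically
#' from `spec$sampler$seed`, so refits with the same spec and data are
#' draw-for-draw identical.
#'
#' @param df validated `avm_tbl` (complete in the moderators the spec uses;
#'   impute first if needed).
#' @param spec [avm_model_spec()].
#' @param tree phylogeny (`phylo`) spanning the data's species; required
#'   when `spec$phylo` and `corr` is not given.
#' @param corr species correlation matrix overriding the tree (dimnames
#'   must cover the data's species); use `diag` for an iid species effect.
#' @param quiet suppress progress output.
#' @return object of class `avm_fit`: `draws` (iteration x chain x
#'   parameter array of core parameters), `u_species` and `p` draw
#'   matrices, pointwise `log_lik`, design metadata for prediction,
#'   `diagnostics` (rank-normalized Rhat / ESS) and a `converged` flag
#'   (`Rhat < 1.01` everywhere); not converging is flagged, not an error.
#' @export
fit_avm <- function(df, spec = avm_model_spec(), tree = NULL, corr = NULL,
                    quiet = TRUE) {
  stopifnot(inherits(spec, "avm_model_spec"))
  df <- if (inherits(df, "avm_tbl")) df else as_avm(df)
  N <- nrow(df)
  x <- df$n_dead
  n <- df$n_caught

  fx <- build_fixed_design(df, spec$fixed, spec$interactions)
  P <- ncol(fx$X)

  splines <- list()
  for (v in spec$spline) {
    if (!v %in% names(df)) abort(paste0("spline covariate not in data: ", v))
    splines[[v]] <- build_spline_design(df[[v]], spec$spline_k, v)
  }

  species_order <- NULL; C <- NULL; L <- NULL; sp_idx <- NULL
  if (spec$phylo) {
    species_order <- sort(unique(df$species))
    if (length(species_order) < 2L) {
      abort("phylogenetic species effect requires >= 2 species")
    }
    if (is.null(corr)) {
      if (is.null(tree)) abort("spec$phylo = TRUE needs a tree or corr matrix")
      C <- brownian_correlation(tree, species_order)
    } else {
      miss <- setdiff(species_order, rownames(corr))
      if (length(miss)) abort(paste0("species missing from corr: ",
                                     paste(miss, collapse = ", ")))
      C <- corr[species_order, species_order]
    }
    L <- chol_corr(C)
    sp_idx <- match(df$species, species_order)
  }

  st_levels <- sort(unique(df$study_id))
  gr_levels <- sort(unique(df$research_group_id))
  has <- list(
    study = "study" %in% spec$group && length(st_levels) > 1L,
    record = "record" %in% spec$group,
    group = "research_group" %in% spec$group && length(gr_levels) > 1L
  )

  jd <- list(x = x, n = n, N = N)
  pr <- spec$priors
  jd$pr_int <- 1 / pr$intercept_scale^2
  jd$df_int <- pr$intercept_df
  jd$pr_beta <- 1 / pr$beta_sd^2

  eta_terms <- "b0"
  decls <- character(0)
  monitors <- c("b0", "p")

  if (P > 0) {
    jd$X <- unname(fx$X); jd$P <- P
    eta_terms <- c(eta_terms, "inprod(X[i,], beta)")
    decls <- c(decls, "for (j in 1:P) { beta[j] ~ dnorm(0, pr_beta) }")
    monitors <- c(monitors, "beta")
  }
  si <- 0
  for (v in names(splines)) {
    si <- si + 1
    sd_ <- splines[[v]]
    lv <- paste0("zlin", si)
    jd[[lv]] <- sd_$linear
    eta_terms <- c(eta_terms, sprintf("bl%d * %s[i]", si, lv))
    decls <- c(decls, sprintf("bl%d ~ dnorm(0, pr_beta)", si))
    monitors <- c(monitors, sprintf("bl%d", si))
    if (!is.null(sd_$Z)) {
      zv <- paste0("Zs", si); kv <- paste0("K", si)
      jd[[zv]] <- unname(sd_$Z); jd[[kv]] <- ncol(sd_$Z)
      eta_terms <- c(eta_terms, sprintf("inprod(%s[i,], bs%d)", zv, si))
      decls <- c(decls, sprintf(
        "for (j in 1:%s) { bs%d[j] ~ dnorm(0, pow(sigma_spl%d, -2)) }\n  sigma_spl%d ~ dt(0, pr_sd, df_sd) T(0,)",
        kv, si, si, si))
      monitors <- c(monitors, sprintf("bs%d", si), sprintf("sigma_spl%d", si))
    }
  }
  if (spec$phylo) {
    # centered parametrization: species intercepts a_sp ~ MVN(b0, sigma^2 C),
    # which mixes far better under Gibbs than the scaled-Cholesky form when
    # species are well sampled
    jd$S <- length(species_order)
    jd$Cinv <- solve(C + diag(avm_chol_jitter(), nrow(C)))
    jd$sp <- sp_idx
    eta_terms <- c(eta_terms, "a_sp[sp[i]]")
    eta_terms <- setdiff(eta_terms, "b0")
    decls <- c(decls, paste0(
      "Omega[1:S,1:S] <- Cinv[,] * pow(sigma_phylo, -2)\n",
      "  for (s in 1:S) { mu_sp[s] <- b0\n",
      "    u_sp[s] <- a_sp[s] - b0 }\n",
      "  a_sp[1:S] ~ dmnorm(mu_sp[], Omega[,])\n",
      "  sigma_phylo ~ dt(0, pr_sd, df_sd) T(0,)"))
    monitors <- c(monitors, "u_sp", "sigma_phylo")
  }
  if (has$study) {
    jd$Nst <- length(st_levels); jd$st <- match(df$study_id, st_levels)
    eta_terms <- c(eta_terms, "u_st[st[i]]")
    decls <- c(decls, paste0(
      "for (j in 1:Nst) { u_st[j] ~ dnorm(0, pow(sigma_study, -2)) }\n",
      "  sigma_study ~ dt(0, pr_sd, df_sd) T(0,)"))
    monitors <- c(monitors, "sigma_study")
  }
  if (has$group) {
    jd$Ngr <- length(gr_levels); jd$gr <- match(df$research_group_id, gr_levels)
    eta_terms <- c(eta_terms, "u_gr[gr[i]]")
    decls <- c(decls, paste0(
      "for (j in 1:Ngr) { u_gr[j] ~ dnorm(0, pow(sigma_group, -2)) }\n",
      "  sigma_group ~ dt(0, pr_sd, df_sd) T(0,)"))
    monitors <- c(monitors, "sigma_group")
  }
  rec_term <- if (has$record) {
    decls <- c(decls, "sigma_record ~ dt(0, pr_sd, df_sd) T(0,)")
    monitors <- c(monitors, "sigma_record")
    "    u_rec[i] ~ dnorm(0, pow(sigma_record, -2))\n"
  } else ""
  if (has$record) eta_terms <- c(eta_terms, "u_rec[i]")

  if (any(grepl("pr_sd", decls, fixed = TRUE))) {
    jd$pr_sd <- 1 / pr$sd_scale^2
    jd$df_sd <- pr$sd_df
  }
  if (!P && !length(splines)) jd$pr_beta <- NULL

  model_str <- paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    x[i] ~ dbin(p[i], n[i])\n",
    "    logit(p[i]) <- ", paste(eta_terms, collapse = " + "), "\n",
    rec_term,
    "  }\n",
    "  b0 ~ dt(0, pr_int, df_int)\n  ",
    paste(decls, collapse = "\n  "),
    "\n}\n"
  )

  smp <- spec$sampler
  chain_seeds <- draw_seeds(smp$seed, smp$chains)
  b0_init <- qlogis((sum(x) + 0.5) / (sum(n) + 1))
  inits <- lapply(seq_len(smp$chains), function(ch) {
    ini <- list(b0 = b0_init,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = chain_seeds[ch])
    for (s in c("sigma_phylo", "sigma_study", "sigma_record", "sigma_group")[
      c(spec$phylo, has$study, has$record, has$group)]) ini[[s]] <- 0.5
    ini
  })

  t0 <- Sys.time()
  # the glm module provides blocked conjugate updates for the
  # linear-Gaussian parts of the logit model, improving mixing markedly
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          inits = inits, n.chains = smp$chains,
                          n.adapt = smp$adapt, quiet = TRUE)
  update(jm, smp$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = unique(monitors),
                              n.iter = smp$iter, progress.bar = "none")
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")

  cn <- colnames(samp[[1]])
  # map JAGS names onto interpretable parameter names; JAGS drops the index
  # suffix for length-1 vectors
  rename <- setNames(cn, cn)
  map_vec <- function(jags_name, k, new_names) {
    if (k == 1L && jags_name %in% cn) rename[jags_name] <<- new_names[1]
    else for (j in seq_len(k)) {
      rename[sprintf("%s[%d]", jags_name, j)] <<- new_names[j]
    }
  }
  if (P > 0) map_vec("beta", P, colnames(fx$X))
  si <- 0
  for (v in names(splines)) {
    si <- si + 1
    rename[sprintf("bl%d", si)] <- paste0("lin_", v)
    if (!is.null(splines[[v]]$Z)) {
      map_vec(sprintf("bs%d", si), ncol(splines[[v]]$Z),
              sprintf("spl_%s[%d]", v, seq_len(ncol(splines[[v]]$Z))))
      rename[sprintf("sigma_spl%d", si)] <- paste0("sigma_spline_", v)
    }
  }

  p_cols <- which(cn == "p" | grepl("^p\\[", cn))
  u_cols <- which(cn == "u_sp" | grepl("^u_sp\\[", cn))
  core_cols <- setdiff(seq_along(cn), c(p_cols, u_cols))

  chains <- lapply(samp, as.matrix)
  iter <- nrow(chains[[1]])
  core_names <- unname(rename[cn[core_cols]])
  draws <- array(NA_real_, dim = c(iter, smp$chains, length(core_cols)),
                 dimnames = list(NULL, NULL, core_names))
  for (ch in seq_len(smp$chains)) draws[, ch, ] <- chains[[ch]][, core_cols]

  p_mat <- do.call(rbind, lapply(chains, function(m) m[, p_cols, drop = FALSE]))
  p_idx <- ifelse(cn[p_cols] == "p", 1L,
                  as.integer(sub("^p\\[(\\d+)\\]$", "\\1", cn[p_cols])))
  p_mat <- p_mat[, order(p_idx), drop = FALSE]
  colnames(p_mat) <- NULL
  total <- nrow(p_mat)
  log_lik <- matrix(dbinom(rep(x, each = total), rep(n, each = total),
                           as.numeric(p_mat), log = TRUE), total, N)

  u_species <- NULL
  if (length(u_cols)) {
    u_species <- do.call(rbind, lapply(chains, function(m) m[, u_cols, drop = FALSE]))
    u_species <- u_species[, order(as.integer(sub("^u_sp\\[(\\d+)\\]$", "\\1",
                                                  cn[u_cols]))), drop = FALSE]
    colnames(u_species) <- species_order
  }

  fit <- structure(list(
    draws = draws, u_species = u_species, p = p_mat, log_lik = log_lik,
    data = df,
    design = list(X = fx$X, terms = fx$terms, xlevels = fx$xlevels,
                  splines = splines),
    groups = list(species = species_order, study = st_levels,
                  research_group = gr_levels, has = has, C = C),
    spec = spec, model_code = model_str, elapsed = elapsed
  ), class = "avm_fit")

  fit$diagnostics <- convergence_report(fit)
  fit$converged <- isTRUE(attr(fit$diagnostics, "pass"))
  if (!fit$converged && !quiet) {
    warn(paste0("Rhat > 1.01 for: ",
                paste(fit$diagnostics$parameter[
                  which(fit$diagnostics$rhat >= 1.01)], collapse = ", ")))
  }
  fit
}

#' @method print avm_fit
#' @export
print.avm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<avm_fit> %d records, %s; %d chains x %d iterations (%.1fs)\n",
              nrow(x$data),
              if (!is.null(x$groups$species))
                paste0(length(x$groups$species), " species") else "no species term",
              d[2], d[1], x$elapsed))
  cat("  parameters:", paste(head(dimnames(x$draws)[[3]], 8), collapse = ", "),
      if (d[3] > 8) "...", "\n")
  cat("  converged (all Rhat < 1.01):", x$converged, "\n")
  invisible(x)
}

n_draws_total <- function(fit) dim(fit$draws)[1] * dim(fit$draws)[2]
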