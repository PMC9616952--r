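#' Simulate a species tree
#'
#' Pure-birth (Yule) trees are rescaled to unit root-to-tip depth so that
#' simulated phylogenetic effect sizes are comparable across species counts;
#' star trees (all tips attached at the root) give species with no shared
#' history, i.e. an identity Brownian correlation.
#'
#' @param n_species number of tips (>= 2).
#' @param model `"yule"` or `"star"`.
#' @param seed RNG seed (Yule topology/branching times).
#' @return ultrametric `phylo` with unit depth.
#' @export
simulate_tree <- function(n_species, model = c("yule", "star"), seed = 1) {
  model <- match.arg(model)
  if (n_species < 2L) abort("n_species must be >= 2")
  if (model == "star") {
    tr <- ape::stree(n_species, type = "star")
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else {
    set.seed(seed)
    tr <- ape::rphylo(n_species, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
  }
  tr$tip.label <- species_to_tip(synthetic_species_names(n_species))
  tr
}

synthetic_species_names <- function(n) {
  genera <- ifelse(seq_len(n) <= ceiling(n / 2), "Synthus", "Parasynthus")
  paste0(genera, " sp", sprintf("%02d", seq_len(n)))
}

#' Simulate an AVM effect-size dataset with known truth
#'
#' Generates study-level haulback-mortality records under the same
#' hierarchical structure the meta-regression assumes: species-level effects
#' drawn from a multivariate Normal with Brownian correlation from the tree,
#' independent Normal study, record and research-group effects, a treatment
#' -coded ocean effect (ocean is assigned per study), optional hook-shape
#' effect, a smooth sinusoidal effect of hooks-between-floats on the logit
#' scale, negative-binomial catch sizes and binomial death counts. Two
#' moderators (hooks between floats, soak duration) can be masked completely
#' at random to emulate the missingness the imputation stage handles.
#'
#' Defaults are sized like a Lamniformes-style clade analysis: 13 species on
#' a unit-depth Yule tree, ~460 records over 40 studies in 6 research
#' groups, two ocean basins.
#'
#' @param tree `phylo`; simulated via [simulate_tree()] when `NULL`.
#' @param n_species tips for the simulated tree when `tree` is `NULL`.
#' @param n_studies number of studies.
#' @param records_per_study inclusive integer range, records drawn uniformly.
#' @param n_groups number of research-group clusters.
#' @param intercept logit-scale baseline mortality.
#' @param beta_ocean logit effect of the Pacific level (Atlantic reference).
#' @param beta_hook logit effect of the J level of hook shape (circle
#'   reference); `unknown` level has effect 0.
#' @param smooth_amplitude amplitude of the sinusoidal hooks-between-floats
#'   effect on the logit scale.
#' @param sigma_phylo,sigma_study,sigma_record,sigma_group group-level
#'   standard deviations (logit scale).
#' @param ocean_probs,hook_probs,bait_probs named category probabilities.
#' @param hbf_range inclusive integer range of hooks between floats.
#' @param catch_mu,catch_size negative-binomial catch-size parameters
#'   (shifted by 1 so every record has at least one capture).
#' @param miss_hbf,miss_soak MCAR masking rates for hooks-between-floats and
#'   soak duration.
#' @param order_name taxonomic order label for the synthetic clade.
#' @param seed RNG seed; all randomness (including the tree) derives from it.
#' @return list with `data` (validated `avm_tbl`, masked cells `NA`) and
#'   `truth` (class `avm_truth`): generating parameters, realized effects,
#'   per-record true probabilities, full unmasked moderators, masks, the
#'   tree, and the implied true phylogenetic signal `lambda`.
#' @export
simulate_avm <- function(tree = NULL, n_species = 13, n_studies = 40,
                         records_per_study = c(8, 15), n_groups = 6,
                         intercept = qlogis(0.35), beta_ocean = 1,
                         beta_hook = 0, smooth_amplitude = 0.3,
                         sigma_phylo = 0.8, sigma_study = 0.5,
                         sigma_record = 0.3, sigma_group = 0.3,
                         ocean_probs = c(Atlantic = 0.5, Pacific = 0.5),
                         hook_probs = c(circle = 0.45, J = 0.45, unknown = 0.1),
                         bait_probs = c(squid = 0.3, fish = 0.4,
                                        mixed = 0.2, unknown = 0.1),
                         hbf_range = c(10, 40), catch_mu = 30,
                         catch_size = 1.2, miss_hbf = 0.04, miss_soak = 0.14,
                         order_name = "Synthiformes", seed = 1) {
  seeds <- draw_seeds(seed, 2L)
  if (is.null(tree)) tree <- simulate_tree(n_species, "yule", seed = seeds[1])
  check_phylo(tree)
  species <- gsub("_", " ", tree$tip.label)
  S <- length(species)

  set.seed(seeds[2])
  C <- brownian_correlation(tree)
  u_sp <- as.numeric(sigma_phylo * (chol_corr(C) %*% rnorm(S)))
  u_st <- rnorm(n_studies, 0, sigma_study)
  u_gr <- rnorm(n_groups, 0, sigma_group)

  study_group <- sample.int(n_groups, n_studies, replace = TRUE)
  study_ocean <- sample(names(ocean_probs), n_studies, replace = TRUE,
                        prob = ocean_probs)
  n_rec <- sample(records_per_study[1]:records_per_study[2], n_studies,
                  replace = TRUE)
  st <- rep.int(seq_len(n_studies), n_rec)
  N <- length(st)

  sp <- sample.int(S, N, replace = TRUE)
  hook_shape <- sample(names(hook_probs), N, replace = TRUE, prob = hook_probs)
  bait <- sample(names(bait_probs), N, replace = TRUE, prob = bait_probs)
  # gear configuration is largely study-specific: hooks-between-floats is a
  # per-study base level with record-level jitter, and soak duration
  # co-varies with it (deeper-set gear soaks longer)
  study_hbf <- runif(n_studies, hbf_range[1], hbf_range[2])
  hbf <- round(study_hbf[st] + rnorm(N, 0, diff(hbf_range) / 10))
  hbf <- pmin(pmax(hbf, hbf_range[1]), hbf_range[2])
  soak <- rlnorm(N, log(8) + 1.2 * (hbf - mean(hbf_range)) / diff(hbf_range),
                 0.15)
  u_rec <- rnorm(N, 0, sigma_record)

  smooth_f <- function(z) {
    smooth_amplitude * sin(2 * pi * (z - hbf_range[1]) /
                             max(1, diff(hbf_range)))
  }
  eta <- intercept +
    beta_ocean * (study_ocean[st] == "Pacific") +
    beta_hook * (hook_shape == "J") +
    smooth_f(hbf) +
    u_sp[sp] + u_st[st] + u_gr[study_group[st]] + u_rec
  p <- plogis(eta)
  clipped <- p < 1e-6 | p > 1 - 1e-6
  if (any(clipped)) {
    warn(sprintf("%d simulated probabilities clipped to (1e-6, 1-1e-6)",
                 sum(clipped)))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  n_caught <- rnbinom(N, mu = catch_mu, size = catch_size) + 1L
  n_dead <- rbinom(N, n_caught, p)

  # species-level traits: body form / ventilation split along the tree order
  trait_half <- seq_len(S) <= ceiling(S / 2)
  body_form <- ifelse(trait_half, "fusiform", "dorsoventrally_flattened")
  vent <- ifelse(trait_half, "ram_obligate", "buccal_facultative")

  genus <- vapply(strsplit(species, " "), `[`, character(1), 1)
  family <- ifelse(genus == "Synthus", "Synthidae", "Parasynthidae")

  mask_hbf <- runif(N) < miss_hbf
  mask_soak <- runif(N) < miss_soak

  df <- tibble::tibble(
    record_id = sprintf("r%04d", seq_len(N)),
    study_id = sprintf("s%02d", st),
    research_group_id = sprintf("g%02d", study_group[st]),
    species = species[sp], genus = genus[sp], family = family[sp],
    order = order_name,
    n_caught = as.integer(n_caught), n_dead = as.integer(n_dead),
    ocean = study_ocean[st], hook_shape = hook_shape,
    hook_type = "unknown",
    hooks_between_floats = ifelse(mask_hbf, NA_real_, as.numeric(hbf)),
    soak_duration = ifelse(mask_soak, NA_real_, soak),
    bait_type = bait, body_form = body_form[sp],
    ventilation_mode = vent[sp]
  )
  data <- as_avm(df)

  sig2 <- c(phylo = sigma_phylo, study = sigma_study,
            record = sigma_record, group = sigma_group)^2
  truth <- structure(list(
    tree = tree, species = species, intercept = intercept,
    beta = c(oceanPacific = beta_ocean, hook_shapeJ = beta_hook),
    smooth_amplitude = smooth_amplitude, smooth_f = smooth_f,
    sigma = sqrt(sig2), lambda = unname(sig2["phylo"] / sum(sig2)),
    u_species = setNames(u_sp, species), u_study = u_st, u_group = u_gr,
    u_record = u_rec, p = p,
    hooks_between_floats_full = as.numeric(hbf), soak_duration_full = soak,
    mask_hbf = mask_hbf, mask_soak = mask_soak, seed = seed
  ), class = "avm_truth")

  list(data = data, truth = truth)
}

#' @method print avm_truth
#' @export
print.avm_truth <- function(x, ...) {
  cat("<avm_truth> ", length(x$p), " records, ", length(x$species),
      " species, seed ", x$seed, "\n", sep = "")
  cat("  intercept ", round(x$intercept, 3), "; beta: ",
      paste(names(x$beta), round(x$beta, 3), sep = "=", collapse = ", "),
      "\n  sigma: ",
      paste(names(x$sigma), round(x$sigma, 3), sep = "=", collapse = ", "),
      "; lambda ", round(x$lambda, 3), "\n", sep = "")
  invisible(x)
}
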