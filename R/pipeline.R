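#' Run the full meta-analytic pipeline from one configuration
#'
#' Orchestrates the stages load/simulate -> clade subset -> moderator
#' screening -> imputation -> Bayesian fit -> posterior summaries ->
#' publication-bias funnel -> sparse-species table, writing tables, a JSON
#' report and a reproducible run manifest under `outdir`. Screening and
#' imputation are skipped automatically when the inputs are complete; all
#' randomness derives from the single `seed`.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   * `dataset`, `tree`: input CSV / tree paths, or `synthetic`: a list of
#'     [simulate_avm()] arguments (one of `dataset` / `synthetic` required);
#'   * `clade`: optional list `order`, `oceans`;
#'   * `model`: optional [avm_model_spec()] argument overrides;
#'   * `screen`: optional list `enabled`, `n_boot`, `threshold`;
#'   * `contrast`: optional list `term`, `level_a`, `level_b`;
#'   * `outdir` (required), `seed`, `profile` (`"ci"` or `"paper"`).
#' @return the run report (named list), invisibly; written as
#'   `report.json` together with `manifest.json`, `dataset.csv`,
#'   `importance.csv` and `summaries.csv` under `outdir`.
#' @export
run_avm_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$outdir)) abort("config$outdir is required")
  seed <- config$seed %||% 1L
  profile <- config$profile %||% "ci"
  seeds <- draw_seeds(seed, 6L)

  # validate inputs before any output is written
  if (!is.null(config$dataset) && !file.exists(config$dataset)) {
    abort(paste0("dataset file not found: ", config$dataset),
          class = "avm_schema_error")
  }
  if (!is.null(config$tree) && !file.exists(config$tree)) {
    abort(paste0("tree file not found: ", config$tree),
          class = "avm_schema_error")
  }
  if (is.null(config$dataset) && is.null(config$synthetic)) {
    abort("config needs either dataset+tree paths or a synthetic block")
  }

  truth <- NULL
  if (!is.null(config$dataset)) {
    df <- read_avm(config$dataset, quiet = TRUE)
    tree <- if (!is.null(config$tree)) {
      select_tree(read_phylo(config$tree), index = config$tree_index,
                  seed = seeds[1])
    }
  } else {
    sim <- do.call(simulate_avm, c(config$synthetic, list(seed = seeds[1])))
    df <- sim$data
    tree <- sim$truth$tree
    truth <- sim$truth
  }

  if (!is.null(config$clade)) {
    df <- subset_clade(df, config$clade$order,
                       config$clade$oceans %||% c("Atlantic", "Pacific"),
                       quiet = TRUE)
  }

  report <- list(seed = seed, profile = profile,
                 load_report = load_report(df))

  scr <- config$screen %||% list()
  importance <- NULL
  if (isTRUE(scr$enabled %||% TRUE)) {
    complete <- names(df)[!vapply(names(df), function(v) anyNA(df[[v]]),
                                  logical(1))]
    cand <- intersect(c("genus", "family", "order", avm_moderators()),
                      complete)
    importance <- screen_predictors(df, candidates = cand,
                                    n_boot = scr$n_boot %||% 30,
                                    threshold = scr$threshold %||% 10,
                                    seed = seeds[2])
    report$screening <- as.list(setNames(importance$importance,
                                         importance$predictor))
  }

  if (anyNA(df$hooks_between_floats) || anyNA(df$soak_duration)) {
    df <- impute_missing(df, seed = seeds[3])
    report$imputation <- list(
      cells_imputed = sum(attr(df, "imputed_cells")),
      oob_trace = attr(df, "oob_trace"))
  }

  margs <- config$model %||% list()
  margs$sampler <- avm_sampler(profile = profile, seed = seeds[4])
  spec <- do.call(avm_model_spec, margs)
  fit <- fit_avm(df, spec, tree = tree)

  report$convergence <- list(
    converged = fit$converged,
    max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
    min_ess_bulk = min(fit$diagnostics$ess_bulk, na.rm = TRUE))

  pool <- pooled_avm(fit)
  report$pooled_avm <- as.list(pool[, c("mean", "hdi_lower", "hdi_upper")])
  if (spec$phylo) {
    sig <- phylo_signal(fit)
    report$phylo_signal <- as.list(sig[, c("mean", "hdi_lower", "hdi_upper")])
  }
  sp_tab <- if (spec$phylo) species_avm(fit) else NULL

  mm_tabs <- list()
  for (term in spec$fixed) {
    mm <- marginal_means(fit, term)
    mm_tabs[[term]] <- mm
    report$marginal_means[[term]] <-
      lapply(split(mm[, c("mean", "hdi_lower", "hdi_upper")], mm$level),
             as.list)
  }
  ctr <- config$contrast
  if (is.null(ctr) && "ocean" %in% spec$fixed) {
    lv <- intersect(c("Atlantic", "Pacific"), unique(df$ocean))
    if (length(lv) == 2L) ctr <- list(term = "ocean", level_a = lv[1],
                                      level_b = lv[2])
  }
  if (!is.null(ctr)) {
    rc <- ratio_contrast(fit, ctr$term, ctr$level_a, ctr$level_b)
    report$ratio_contrast <- as.list(rc[, c("quantity", "mean", "hdi_lower",
                                            "hdi_upper", "prob_gt_1")])
  }

  funnel <- tryCatch(funnel_analysis(df), error = function(e) NULL)
  if (!is.null(funnel)) {
    report$funnel <- list(pooled_logit = funnel$pooled_logit,
                          slope = funnel$slope, p_value = funnel$p_value,
                          asymmetric = funnel$asymmetric)
  }
  sparse_tab <- sparse_species_table(df)
  if (!is.null(truth)) {
    report$truth <- list(intercept = truth$intercept,
                         beta = as.list(truth$beta),
                         sigma = as.list(truth$sigma),
                         lambda = truth$lambda)
  }

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_avm(df, file.path(config$outdir, "dataset.csv"))
  if (!is.null(importance)) {
    readr::write_csv(tibble::as_tibble(importance),
                     file.path(config$outdir, "importance.csv"),
                     progress = FALSE)
  }
  summaries <- dplyr::bind_rows(
    dplyr::mutate(pool, table = "pooled"),
    if (spec$phylo) dplyr::mutate(phylo_signal(fit), table = "signal"),
    if (!is.null(sp_tab)) dplyr::mutate(sp_tab, table = "species",
                                        quantity = .data$species)
  )
  readr::write_csv(summaries, file.path(config$outdir, "summaries.csv"),
                   progress = FALSE)
  if (!is.null(sparse_tab) && nrow(sparse_tab)) {
    readr::write_csv(sparse_tab, file.path(config$outdir, "sparse_species.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config = config[setdiff(names(config), "outdir")],
    seed = seed, stage_seeds = seeds,
    package_version = as.character(utils::packageVersion("avmmeta")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Replicate the clade-level analysis workflow on a deposited database
#'
#' Convenience driver for rerunning the full clade analysis on an external
#' effect-size database and tree file: reads and validates the data,
#' subsets one taxonomic order to the requested ocean basins, imputes any
#' missing gear moderators, fits the phylogenetically adjusted
#' meta-regression and returns the headline quantities (pooled rate,
#' phylogenetic signal, ocean marginal means and ratio, species rates,
#' funnel diagnostics).
#'
#' @param dataset_csv effect-size CSV readable by [read_avm()].
#' @param tree_file Newick/NEXUS tree (sets of trees allowed;
#'   `tree_index` picks one).
#' @param order_name taxonomic order to analyse.
#' @param oceans_keep ocean basins retained.
#' @param tree_index index into a multi-tree file (random if `NULL`).
#' @param spec model specification; defaults to the canonical clade model
#'   (ocean + hook shape fixed effects with interaction, smooth in hooks
#'   between floats, phylogenetic + study/record/research-group terms).
#' @param col_map column mapping for the CSV.
#' @param seed root seed.
#' @return list: `fit`, `pooled`, `signal`, `species`, `marginal_ocean`,
#'   `ocean_ratio`, `funnel`, `load_report`.
#' @export
replicate_clade_analysis <- function(dataset_csv, tree_file, order_name,
                                     oceans_keep = c("Atlantic", "Pacific"),
                                     tree_index = NULL, spec = NULL,
                                     col_map = avm_cols(), seed = 1) {
  seeds <- draw_seeds(seed, 3L)
  df <- read_avm(dataset_csv, col_map = col_map, quiet = TRUE)
  clade <- subset_clade(df, order_name, oceans_keep, quiet = TRUE)
  tree <- select_tree(read_phylo(tree_file), index = tree_index,
                      seed = seeds[1])
  if (anyNA(clade$hooks_between_floats) || anyNA(clade$soak_duration)) {
    clade <- impute_missing(clade, seed = seeds[2])
  }
  if (is.null(spec)) {
    spec <- avm_model_spec(
      fixed = c("ocean", "hook_shape"),
      interactions = "ocean:hook_shape",
      spline = "hooks_between_floats",
      sampler = avm_sampler("paper", seed = seeds[3]))
  }
  fit <- fit_avm(clade, spec, tree = tree)
  lv <- intersect(c("Atlantic", "Pacific"), unique(clade$ocean))
  list(
    fit = fit,
    pooled = pooled_avm(fit),
    signal = phylo_signal(fit),
    species = species_avm(fit),
    marginal_ocean = if ("ocean" %in% spec$fixed) marginal_means(fit, "ocean"),
    ocean_ratio = if (length(lv) == 2L)
      ratio_contrast(fit, "ocean", lv[1], lv[2]),
    funnel = tryCatch(funnel_analysis(clade), error = function(e) NULL),
    load_report = load_report(clade)
  )
}
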