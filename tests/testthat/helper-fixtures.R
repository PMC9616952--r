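# shared fixtures: tiny hand-built tables and one memoised small model fit
# so multiple test files can reuse it without refitting

.fixture_env <- new.env(parent = emptyenv())

tiny_avm_df <- function() {
  tibble::tibble(
    record_id = paste0("r", 1:6),
    study_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    research_group_id = c("g1", "g1", "g1", "g1", "g2", "g2"),
    species = c("Synthus sp01", "Synthus sp01", "Synthus sp02",
                "Synthus sp02", "Parasynthus sp03", "Parasynthus sp03"),
    genus = c("Synthus", "Synthus", "Synthus", "Synthus",
              "Parasynthus", "Parasynthus"),
    family = c(rep("Synthidae", 4), rep("Parasynthidae", 2)),
    order = c(rep("Synthiformes", 4), rep("Parasynthiformes", 2)),
    n_caught = c(20L, 15L, 30L, 10L, 25L, 40L),
    n_dead = c(5L, 3L, 12L, 0L, 20L, 35L),
    ocean = c("Atlantic", "Atlantic", "Pacific", "Pacific",
              "Atlantic", "Mediterranean"),
    hook_shape = c("circle", "J", "circle", "J", "circle", "J"),
    hooks_between_floats = c(25, 25, 18, 18, 30, 30),
    soak_duration = c(10.5, 9, 11, 12, 8.5, 11),
    bait_type = c("squid", "fish", "squid", "mixed", "fish", "squid")
  )
}

# small complete synthetic clade + fitted model, computed once per test run
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_avm(
      n_species = 8, n_studies = 16, records_per_study = c(6, 9),
      miss_hbf = 0, miss_soak = 0, seed = 301)
  }
  .fixture_env$sim
}

small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- small_sim()
    spec <- avm_model_spec(
      fixed = "ocean", spline = "hooks_between_floats", spline_k = 8,
      sampler = avm_sampler("ci", chains = 2, iter = 400, warmup = 300,
                            seed = 99))
    .fixture_env$fit <- fit_avm(sim$data, spec, tree = sim$truth$tree)
  }
  .fixture_env$fit
}

write_newick <- function(txt) {
  path <- tempfile(fileext = ".nwk")
  writeLines(txt, path)
  path
}
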