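test_that("packaged example CSV loads with expected counts", {
  path <- system.file("extdata", "synthetic_example.csv", package = "avmmeta")
  df <- read_avm(path, quiet = TRUE)
  rep <- load_report(df)
  expect_s3_class(df, "avm_tbl")
  expect_equal(rep$records, 6)
  expect_equal(rep$species, 3)
  expect_equal(rep$orders, 2)
  # blank categorical cells become explicit unknown levels, numeric stay NA
  expect_equal(df$hook_type[4], "unknown")
  expect_true(is.na(df$soak_duration[3]))
  expect_true(is.na(df$hooks_between_floats[5]))
})

test_that("load report counts match an independent group-by of the raw CSV", {
  path <- system.file("extdata", "synthetic_example.csv", package = "avmmeta")
  raw <- readr::read_csv(path, show_col_types = FALSE)
  rep <- load_report(read_avm(path, quiet = TRUE))
  expect_equal(rep$records, nrow(raw))
  expect_equal(rep$species, length(unique(raw$species)))
  expect_equal(rep$genera, length(unique(raw$genus)))
  expect_equal(rep$families, length(unique(raw$family)))
  expect_equal(rep$orders, length(unique(raw$order)))
  expect_equal(rep$studies, length(unique(raw$study_id)))
})

test_that("invalid records are rejected with row-level diagnostics", {
  df <- tiny_avm_df()
  df$n_dead[2] <- 99L                       # n_dead > n_caught
  expect_error(as_avm(df), "r2", class = "avm_validation_error")

  df2 <- tiny_avm_df()
  df2$n_caught[3] <- 0L                     # zero catch rejected, not imputed
  expect_error(as_avm(df2), "r3", class = "avm_validation_error")

  df3 <- tiny_avm_df()
  df3$record_id[4] <- "r1"                  # duplicate id
  expect_error(as_avm(df3), "duplicate", class = "avm_validation_error")

  df4 <- tiny_avm_df()
  df4$genus[2] <- "Wrongus"                 # two taxonomies for one species
  expect_error(as_avm(df4), "inconsistent taxonomy")

  # drop mode removes only the offending rows
  df5 <- tiny_avm_df()
  df5$n_dead[2] <- 99L
  expect_warning(out <- as_avm(df5, on_invalid = "drop"), "dropping")
  expect_equal(nrow(out), 5)
  expect_false("r2" %in% out$record_id)
})

test_that("schema errors name the missing column", {
  df <- tiny_avm_df()
  df$n_caught <- NULL
  expect_error(as_avm(df), "n_caught", class = "avm_schema_error")
  expect_error(read_avm(tempfile(fileext = ".csv")),
               class = "avm_schema_error")
})

test_that("column mapping renames arbitrary headers", {
  df <- tiny_avm_df()
  names(df)[names(df) == "n_caught"] <- "total"
  names(df)[names(df) == "n_dead"] <- "dead"
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  out <- read_avm(path, col_map = avm_cols(n_caught = "total",
                                           n_dead = "dead"), quiet = TRUE)
  expect_equal(out$n_caught, tiny_avm_df()$n_caught)
  expect_error(avm_cols(not_a_field = "x"), "unknown field")
})

test_that("write/read round-trips a valid dataset", {
  df <- as_avm(tiny_avm_df())
  path <- tempfile(fileext = ".csv")
  write_avm(df, path)
  back <- read_avm(path, quiet = TRUE)
  cols <- c("record_id", "study_id", "species", "n_caught", "n_dead",
            "ocean", "hook_shape", "bait_type", "hooks_between_floats")
  expect_equal(as.data.frame(back[, cols]), as.data.frame(df[, cols]))
})

test_that("species names are normalized before use", {
  df <- tiny_avm_df()
  df$species[1] <- "  synthus   SP01 "
  out <- as_avm(df)
  expect_equal(out$species[1], "Synthus sp01")
})

test_that("subset_clade filters by order and ocean with an audit trail", {
  df <- as_avm(tiny_avm_df())
  expect_message(
    out <- subset_clade(df, "Synthiformes", c("Atlantic", "Pacific"),
                        quiet = FALSE),
    regexp = NA)                      # nothing excluded within this order
  expect_equal(nrow(out), 4)
  expect_true(all(out$order == "Synthiformes"))
  expect_true(all(out$record_id %in% df$record_id))     # always a subset

  expect_message(
    med <- subset_clade(df, "Parasynthiformes", "Atlantic", quiet = FALSE),
    "Mediterranean=1")
  expect_equal(nrow(med), 1)

  expect_error(subset_clade(df, "Nosuchiformes"), "order not present")
  expect_error(subset_clade(df, "Synthiformes", "Indian"),
               class = "avm_empty_subset_error")
})

test_that("raw_avm_rate returns exact proportions", {
  expect_equal(raw_avm_rate(0, 10), 0)
  expect_equal(raw_avm_rate(10, 10), 1)
  expect_equal(raw_avm_rate(3, 8), 0.375)
  out <- raw_avm_rate(as_avm(tiny_avm_df()))
  expect_equal(out$avm_rate, out$n_dead / out$n_caught)
})
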