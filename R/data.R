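#' Default column mapping for AVM effect-size tables
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a CSV on disk. Override individual entries to read files with
#' different headers, e.g. `avm_cols(n_caught = "total", n_dead = "dead")`.
#'
#' @param ... named character scalars overriding default header names.
#' @return Named character vector mapping canonical field -> CSV header.
#' @export
avm_cols <- function(...) {
  def <- c(
    record_id = "record_id", study_id = "study_id",
    research_group_id = "research_group_id",
    species = "species", genus = "genus", family = "family", order = "order",
    n_caught = "n_caught", n_dead = "n_dead",
    ocean = "ocean", hook_shape = "hook_shape", hook_type = "hook_type",
    hooks_between_floats = "hooks_between_floats",
    soak_duration = "soak_duration", bait_type = "bait_type",
    body_form = "body_form", ventilation_mode = "ventilation_mode"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(def))
    if (length(bad)) abort(paste0("unknown field(s): ", paste(bad, collapse = ", ")))
    def[names(dots)] <- dots
  }
  def
}

avm_required_fields <- function() {
  c("record_id", "study_id", "species", "n_caught", "n_dead")
}

avm_ocean_levels <- function() {
  c("Atlantic", "Pacific", "Indian", "Mediterranean", "BlackSea", "Unknown")
}

avm_categorical_fields <- function() {
  c("ocean", "hook_shape", "hook_type", "bait_type", "body_form",
    "ventilation_mode")
}

avm_moderators <- function() {
  c("ocean", "hook_shape", "hook_type", "hooks_between_floats",
    "soak_duration", "bait_type", "body_form", "ventilation_mode")
}

#' Coerce and validate an AVM effect-size table
#'
#' Normalises species names, maps blank/missing categorical cells to explicit
#' `"unknown"` levels (`"Unknown"` for ocean), coerces counts to integers and
#' checks the record invariants: `n_caught >= 1`, `0 <= n_dead <= n_caught`,
#' unique `record_id`, non-empty `study_id` and `species`, and a single
#' genus/family/order assignment per species.
#'
#' @param df data frame with (at least) the required effect-size columns.
#' @param on_invalid `"error"` (default) aborts listing the offending
#'   `record_id`s; `"drop"` removes offending rows with a warning.
#' @return A validated tibble of class `avm_tbl` with a `load_report`
#'   attribute (see [load_report()]).
#' @export
as_avm <- function(df, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- tibble::as_tibble(df)

  miss <- setdiff(avm_required_fields(), names(df))
  if (length(miss)) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
          class = "avm_schema_error")
  }

  for (f in c("record_id", "study_id")) df[[f]] <- as.character(df[[f]])
  if (!"research_group_id" %in% names(df)) df$research_group_id <- df$study_id
  df$research_group_id <- as.character(df$research_group_id)

  df$species <- normalize_species(df$species)
  if (!"genus" %in% names(df)) {
    df$genus <- vapply(strsplit(df$species, " "), `[`, character(1), 1)
  }
  for (f in c("genus", "family", "order")) {
    if (!f %in% names(df)) df[[f]] <- "Unknown"
    df[[f]] <- trimws(as.character(df[[f]])) %na% "Unknown"
    df[[f]][!nzchar(df[[f]])] <- "Unknown"
  }

  suppressWarnings({
    df$n_caught <- as.integer(round(as.numeric(df$n_caught)))
    df$n_dead <- as.integer(round(as.numeric(df$n_dead)))
  })

  for (f in avm_categorical_fields()) {
    unk <- if (f == "ocean") "Unknown" else "unknown"
    if (!f %in% names(df)) df[[f]] <- unk
    df[[f]] <- trimws(as.character(df[[f]]))
    df[[f]][is.na(df[[f]]) | !nzchar(df[[f]])] <- unk
  }
  bad_ocean <- !df$ocean %in% avm_ocean_levels()
  if (any(bad_ocean)) {
    warn(paste0("unrecognised ocean value(s) mapped to Unknown: ",
                paste(unique(df$ocean[bad_ocean]), collapse = ", ")))
    df$ocean[bad_ocean] <- "Unknown"
  }

  for (f in c("hooks_between_floats", "soak_duration")) {
    if (!f %in% names(df)) df[[f]] <- NA_real_
    suppressWarnings(df[[f]] <- as.numeric(df[[f]]))
    df[[f]][!is.na(df[[f]]) & df[[f]] <= 0] <- NA_real_
  }

  problems <- character(0)
  flag <- function(bad, why) {
    if (any(bad, na.rm = TRUE)) {
      ids <- df$record_id[which(bad)]
      problems <<- c(problems, paste0(why, ": ", paste(ids, collapse = ", ")))
      bad
    } else rep(FALSE, nrow(df))
  }
  bad <- flag(is.na(df$n_caught) | df$n_caught < 1L, "n_caught missing or < 1")
  bad <- bad | flag(is.na(df$n_dead) | df$n_dead < 0L, "n_dead missing or negative")
  bad <- bad | flag(!is.na(df$n_dead) & !is.na(df$n_caught) &
                      df$n_dead > df$n_caught, "n_dead > n_caught")
  bad <- bad | flag(is.na(df$species) | !nzchar(df$species %na% ""),
                    "empty species")
  bad <- bad | flag(!nzchar(df$study_id %na% ""), "empty study_id")
  dup <- duplicated(df$record_id) | duplicated(df$record_id, fromLast = TRUE)
  bad <- bad | flag(dup & duplicated(df$record_id), "duplicate record_id")

  if (any(bad)) {
    msg <- paste0("invalid record(s):\n  ", paste(problems, collapse = "\n  "))
    if (on_invalid == "error") abort(msg, class = "avm_validation_error")
    warn(paste0("dropping ", sum(bad), " record(s)\n", msg))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) abort("no valid records", class = "avm_validation_error")

  tax <- dplyr::distinct(df, .data$species, .data$genus, .data$family, .data$order)
  dup_tax <- tax$species[duplicated(tax$species)]
  if (length(dup_tax)) {
    abort(paste0("inconsistent taxonomy for species: ",
                 paste(unique(dup_tax), collapse = ", ")),
          class = "avm_validation_error")
  }

  df <- new_avm_tbl(df)
  attr(df, "load_report") <- compute_load_report(df, n_rejected = sum(bad))
  df
}

new_avm_tbl <- function(df) {
  class(df) <- unique(c("avm_tbl", class(tibble::as_tibble(df))))
  df
}

compute_load_report <- function(df, n_rejected = 0L) {
  list(
    records = nrow(df),
    species = dplyr::n_distinct(df$species),
    genera = dplyr::n_distinct(df$genus),
    families = dplyr::n_distinct(df$family),
    orders = dplyr::n_distinct(df$order),
    studies = dplyr::n_distinct(df$study_id),
    research_groups = dplyr::n_distinct(df$research_group_id),
    rejected = as.integer(n_rejected)
  )
}

#' Load report of a validated AVM table
#'
#' @param df an `avm_tbl` (or any effect-size data frame, recomputed on the
#'   fly).
#' @return A list with record/species/genus/family/order/study counts.
#' @export
load_report <- function(df) {
  rep <- attr(df, "load_report")
  if (is.null(rep)) rep <- compute_load_report(tibble::as_tibble(df))
  rep
}

#' Read an AVM effect-size CSV
#'
#' Reads a UTF-8 CSV with a header row, renames columns according to
#' `col_map`, validates the records and reports load counts to stderr.
#'
#' @param path CSV file path.
#' @param col_map column mapping from [avm_cols()].
#' @param on_invalid passed to [as_avm()].
#' @param quiet suppress the load report message.
#' @return validated `avm_tbl`.
#' @export
read_avm <- function(path, col_map = avm_cols(), on_invalid = "error",
                     quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "avm_schema_error")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- col_map[avm_required_fields()]
  miss <- need[!need %in% names(raw)]
  if (length(miss)) {
    abort(paste0("column(s) not found in ", path, ": ",
                 paste(miss, collapse = ", ")), class = "avm_schema_error")
  }
  present <- col_map[col_map %in% names(raw)]
  raw <- dplyr::rename(raw, !!!setNames(unname(present), names(present)))
  out <- as_avm(raw, on_invalid = on_invalid)
  if (!quiet) {
    r <- load_report(out)
    inform(sprintf(
      "loaded %d records: %d species, %d genera, %d families, %d orders (%d rejected)",
      r$records, r$species, r$genera, r$families, r$orders, r$rejected))
  }
  out
}

#' Write an AVM effect-size table to CSV
#'
#' Inverse of [read_avm()] under the default column mapping: reading the
#' written file back yields the same records.
#'
#' @param df `avm_tbl` or compatible data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_avm <- function(df, path) {
  cols <- intersect(names(avm_cols()), names(df))
  readr::write_csv(tibble::as_tibble(df)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Subset an AVM table to one taxonomic order and a set of ocean basins
#'
#' Mirrors the clade-level analysis datasets: records of a single order,
#' restricted to the ocean basins with adequate coverage (records from other
#' basins, e.g. Mediterranean and Indian Ocean, are excluded and counted).
#'
#' @param df validated `avm_tbl`.
#' @param order_name taxonomic order, e.g. `"Carcharhiniformes"`.
#' @param oceans_keep character vector of ocean levels to retain.
#' @param quiet suppress the per-ocean removal message.
#' @return `avm_tbl` subset (refreshed load report).
#' @export
subset_clade <- function(df, order_name,
                         oceans_keep = c("Atlantic", "Pacific"),
                         quiet = FALSE) {
  if (!order_name %in% df$order) {
    abort(paste0("order not present in data: ", order_name))
  }
  bad_ocean <- setdiff(oceans_keep, avm_ocean_levels())
  if (length(bad_ocean)) abort(paste0("unknown ocean level(s): ",
                                      paste(bad_ocean, collapse = ", ")))
  clade <- df[df$order == order_name, , drop = FALSE]
  removed <- clade[!clade$ocean %in% oceans_keep, , drop = FALSE]
  out <- clade[clade$ocean %in% oceans_keep, , drop = FALSE]
  if (!quiet && nrow(removed)) {
    tab <- table(removed$ocean)
    inform(paste0("excluded ", nrow(removed), " record(s) by ocean: ",
                  paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
  if (nrow(out) == 0L) {
    abort(paste0("empty subset for ", order_name, " in ",
                 paste(oceans_keep, collapse = "/")),
          class = "avm_empty_subset_error")
  }
  out <- new_avm_tbl(out)
  attr(out, "load_report") <- compute_load_report(out)
  out
}

#' Raw at-vessel mortality proportion
#'
#' `n_dead / n_caught`, vectorised. Given a data frame first argument,
#' returns the data frame with an `avm_rate` column appended; given two
#' count vectors, returns the proportions.
#'
#' @param x data frame with `n_dead`, `n_caught` columns, or a dead-count
#'   vector.
#' @param n caught-count vector (when `x` is a vector).
#' @return tibble with `avm_rate`, or numeric vector in `[0, 1]`.
#' @export
raw_avm_rate <- function(x, n = NULL) {
  if (is.data.frame(x)) {
    dplyr::mutate(x, avm_rate = .data$n_dead / .data$n_caught)
  } else {
    stopifnot(all(x >= 0 & x <= n))
    x / n
  }
}
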