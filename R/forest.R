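#' Forest plot of study-level effects for one species
#'
#' Study-level estimates on the log relative-risk scale (each record's
#' continuity-corrected proportion relative to the pooled rate), ordered by
#' effect size, with a pooled-effect row and dashed pooled line; optionally
#' split into panels by a moderator (e.g. squid-only bait versus other).
#' The pooled rate comes from `fit` ([pooled_avm()]) when supplied, else
#' from an inverse-variance random-effects pool of the records on the logit
#' scale (per panel when `split_by` is given).
#'
#' @param df single-species `avm_tbl` subset with >= 2 records.
#' @param fit optional `avm_fit` on the same records.
#' @param split_by optional moderator column used to facet the plot and
#'   pool separately.
#' @param mass interval mass for record-level intervals.
#' @return object of class `avm_forest`: `table` (per-record rows plus
#'   pooled rows, ordered by effect), `pooled` (per-panel pooled
#'   proportions), and a ggplot in `$plot` (also via `autoplot()`).
#' @export
forest_plot <- function(df, fit = NULL, split_by = NULL, mass = 0.95) {
  if (dplyr::n_distinct(df$species) != 1L) {
    abort("forest_plot expects a single-species subset")
  }
  if (nrow(df) < 2L) abort("need at least 2 records")
  z <- qnorm(1 - (1 - mass) / 2)
  panel <- if (is.null(split_by)) rep("all", nrow(df)) else as.character(df[[split_by]])

  rows <- tibble::tibble(
    record_id = df$record_id, study_id = df$study_id, panel = panel,
    x = df$n_dead, n = df$n_caught,
    p_hat = (df$n_dead + 0.5) / (df$n_caught + 1),
    yi = logit_cc(df$n_dead, df$n_caught),
    se = sqrt(var_logit_cc(df$n_dead, df$n_caught))
  )

  pooled <- purrr::map_dfr(unique(rows$panel), function(pn) {
    r <- rows[rows$panel == pn, ]
    if (!is.null(fit) && is.null(split_by)) {
      pp <- pooled_avm(fit)
      tibble::tibble(panel = pn, p_pool = pp$mean,
                     lower = pp$hdi_lower, upper = pp$hdi_upper,
                     source = "model")
    } else {
      tau2 <- dl_tau2(r$yi, r$se^2)
      w <- 1 / (r$se^2 + tau2)
      mu <- sum(w * r$yi) / sum(w)
      se_mu <- sqrt(1 / sum(w))
      tibble::tibble(panel = pn, p_pool = plogis(mu),
                     lower = plogis(mu - z * se_mu),
                     upper = plogis(mu + z * se_mu),
                     source = "inverse-variance")
    }
  })

  rows <- dplyr::left_join(rows, pooled[, c("panel", "p_pool")], by = "panel")
  rows <- dplyr::mutate(rows,
    log_rr = log(.data$p_hat / .data$p_pool),
    log_rr_lower = log(plogis(.data$yi - z * .data$se) / .data$p_pool),
    log_rr_upper = log(plogis(.data$yi + z * .data$se) / .data$p_pool))
  rows <- dplyr::arrange(rows, .data$panel, .data$log_rr)

  tab <- dplyr::bind_rows(
    dplyr::mutate(rows, row_type = "record"),
    dplyr::mutate(pooled, record_id = "POOLED", row_type = "pooled",
                  log_rr = 0, p_hat = .data$p_pool,
                  log_rr_lower = log(.data$lower / .data$p_pool),
                  log_rr_upper = log(.data$upper / .data$p_pool))
  )

  plot_df <- dplyr::group_by(tab, .data$panel)
  plot_df <- dplyr::mutate(plot_df,
    y = dplyr::row_number() + (.data$row_type == "pooled"))
  plot_df <- dplyr::ungroup(plot_df)
  gg <- ggplot2::ggplot(plot_df,
                        ggplot2::aes(x = .data$log_rr, y = .data$y)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$log_rr_lower,
                                         xmax = .data$log_rr_upper),
                            height = 0, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$row_type,
                                     size = .data$row_type)) +
    ggplot2::scale_shape_manual(values = c(record = 15, pooled = 18)) +
    ggplot2::scale_size_manual(values = c(record = 2, pooled = 4)) +
    ggplot2::scale_y_continuous(breaks = plot_df$y,
                                labels = plot_df$record_id) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "log relative risk vs pooled rate", y = NULL,
                  title = unique(df$species)) +
    ggplot2::guides(size = "none", shape = "none") +
    ggplot2::theme_minimal()

  structure(list(table = tab, pooled = pooled, plot = gg,
                 species = unique(df$species)), class = "avm_forest")
}

#' @method print avm_forest
#' @export
print.avm_forest <- function(x, ...) {
  cat("<avm_forest> ", x$species, ": ",
      sum(x$table$row_type == "record"), " records, ",
      nrow(x$pooled), " panel(s)\n", sep = "")
  print(x$pooled)
  invisible(x)
}

#' @export
autoplot.avm_forest <- function(object, ...) object$plot

# DerSimonian-Laird between-study variance on the logit scale
dl_tau2 <- function(yi, vi) {
  w <- 1 / vi
  mu <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu)^2)
  k <- length(yi)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (Q - (k - 1)) / denom)
}
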