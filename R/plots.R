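# ggplot2 views of the main result objects.

#' Stacked relative-abundance plot of an ensemble
#'
#' One stacked bar of final relative abundances per replicate, the
#' standard way to eyeball replicate-to-replicate variability after
#' stochastic inoculation.
#'
#' @param object A `sim_ensemble`.
#' @param top_n Taxa beyond the `top_n` most abundant are pooled into
#'   "other". Default 12.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_ensemble <- function(object, top_n = 12, ...) {
  res <- object$results
  keep <- res |>
    group_by(.data$taxon_id) |>
    summarise(total = sum(.data$rel_abundance), .groups = "drop") |>
    arrange(desc(.data$total)) |>
    head(top_n) |>
    pull(.data$taxon_id)
  res |>
    mutate(taxon = ifelse(.data$taxon_id %in% keep, .data$taxon_id,
                          "other")) |>
    group_by(.data$replicate, .data$taxon) |>
    summarise(rel_abundance = sum(.data$rel_abundance),
              .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$replicate),
                                 y = .data$rel_abundance,
                                 fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "replicate", y = "relative abundance",
                  fill = "taxon") +
    ggplot2::theme_minimal()
}

#' Trajectory plot of a serial-transfer run
#'
#' Per-cycle final community size (log10) across growth/dilution cycles.
#'
#' @param object A `cycle_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cycle_trajectory <- function(object, ...) {
  object$totals |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cycle, y = .data$final_size)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "growth/dilution cycle",
                  y = "final community size (cells)") +
    ggplot2::theme_minimal()
}

#' Gate view of a flow-cytometry event table
#'
#' Scatter of events on FSC-H / FITC-H (log10) with the gate thresholds
#' drawn as dashed lines.
#'
#' @param events Event tibble with `FSC-H` and `FITC-H`.
#' @param fsc_min,fitc_min Gate thresholds. Defaults 50 and 350.
#' @return A ggplot object.
#' @export
plot_fcm_gate <- function(events, fsc_min = 50, fitc_min = 350) {
  gated <- events[["FSC-H"]] > fsc_min & events[["FITC-H"]] > fitc_min
  events$gated <- ifelse(gated, "gated", "excluded")
  ggplot2::ggplot(events, ggplot2::aes(x = .data[["FSC-H"]],
                                       y = .data[["FITC-H"]],
                                       colour = .data$gated)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_vline(xintercept = fsc_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = fitc_min, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}

#' Rank-abundance plot of a taxon pool
#'
#' @param pool A [taxon_pool()].
#' @return A ggplot object (log10 abundance vs rank).
#' @export
plot_rank_abundance <- function(pool) {
  validate_taxon_pool(pool)
  d <- tibble(rank = seq_len(nrow(pool)),
              rel_abundance = sort(pool$rel_abundance, decreasing = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank,
                                  y = .data$rel_abundance)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "relative abundance") +
    ggplot2::theme_minimal()
}
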