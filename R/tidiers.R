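# broom-style tidiers for the simulation result objects.

#' @exportS3Method generics::tidy
tidy.batch_sim <- function(x, ...) {
  x$state |>
    mutate(rel_abundance = .data$n_final / sum(.data$n_final)) |>
    as_tibble()
}

#' @exportS3Method generics::glance
glance.batch_sim <- function(x, ...) {
  tibble(
    n_taxa = nrow(x$state),
    n_taxa_grown = sum(x$state$n_final > x$state$n0),
    total_n0 = sum(x$state$n0),
    total_final = sum(x$state$n_final),
    substrate_final = x$substrate,
    time_h = x$time,
    mass_balance_error = x$mass_balance_error
  )
}

#' @exportS3Method base::print
print.batch_sim <- function(x, ...) {
  cat(sprintf(
    "<batch_sim> %d taxa: %.3g -> %.3g cells in %.1f h (substrate left %.2g g C)\n",
    nrow(x$state), sum(x$state$n0), sum(x$state$n_final), x$time,
    x$substrate))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sim_ensemble <- function(x, ...) {
  as_tibble(x$results)
}

#' @exportS3Method generics::glance
glance.sim_ensemble <- function(x, ...) {
  x$results |>
    group_by(replicate = .data$replicate) |>
    summarise(
      total_final = sum(.data$final_count),
      inoc_total = sum(.data$inoc_count),
      richness_reads = sum(.data$reads > 0),
      shannon = shannon(.data$rel_abundance /
                          sum(.data$rel_abundance)),
      .groups = "drop"
    )
}

#' @exportS3Method base::print
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %d replicates x %d taxa\n",
              length(x$seeds), dplyr::n_distinct(x$results$taxon_id)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cycle_trajectory <- function(x, ...) {
  as_tibble(x$results)
}

#' @exportS3Method generics::glance
glance.cycle_trajectory <- function(x, ...) {
  x$results |>
    group_by(cycle = .data$cycle) |>
    summarise(
      total_final = sum(.data$count),
      richness_reads = sum(.data$reads > 0),
      .groups = "drop"
    ) |>
    mutate(extinct = x$extinct)
}

#' @exportS3Method base::print
print.cycle_trajectory <- function(x, ...) {
  cat(sprintf("<cycle_trajectory> %d cycle(s)%s\n",
              nrow(x$totals),
              if (x$extinct) " [extinct before completion]" else ""))
  invisible(x)
}
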