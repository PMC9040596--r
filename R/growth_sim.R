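#' Growth parameters for carbon-limited batch growth
#'
#' Stoichiometry and kinetics of the shared-substrate Monod model. Defaults
#' reflect a soil-extract-amended silt microcosm: 200 fg carbon per cell,
#' a 20% carbon-to-biomass yield, and a per-batch carbon pool sized so that
#' a 2e5-cell inoculum grows to roughly 2e8 cells.
#'
#' @param S0 Initial substrate carbon per batch (g C). Default `2e-4`.
#' @param K_s Half-saturation constant (g C, same volume basis as `S0`).
#'   Default `0.05 * S0`. Kinetic only: it shapes trajectories and final
#'   composition, not the final total (stoichiometric) community size.
#' @param Y Yield, g biomass-C per g substrate-C, in (0, 1]. Default 0.2.
#' @param c_cell Carbon per cell (g C). Default `2e-13` (200 fg).
#' @return A list of class `growth_params`.
#' @examples
#' growth_params()
#' @export
growth_params <- function(S0 = 2e-4, K_s = if (S0 > 0) 0.05 * S0 else 1e-5,
                          Y = 0.2, c_cell = 2e-13) {
  assert_scalar_number(S0, "S0", min = 0)
  assert_scalar_number(K_s, "K_s", min = 0, strict_min = TRUE)
  assert_scalar_number(Y, "Y", min = 0, max = 1, strict_min = TRUE)
  assert_scalar_number(c_cell, "c_cell", min = 0, strict_min = TRUE)
  structure(list(S0 = S0, K_s = K_s, Y = Y, c_cell = c_cell),
            class = "growth_params")
}

validate_growth_params <- function(params) {
  assert_that(inherits(params, "growth_params"),
              "`params` must be created with `growth_params()`.")
  invisible(params)
}

#' Sample a finite inoculum from a taxon pool
#'
#' Draws `n_cells` individual cells multinomially with probabilities equal
#' to the pool's relative abundances — the finite-sampling bottleneck that
#' makes rare taxa present or absent by chance in replicate inoculations.
#'
#' @param pool A [taxon_pool()].
#' @param n_cells Number of cells to draw. Default `2e5`.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A tibble of class `inoculum` with columns `taxon_id`, `count`
#'   (integers summing to `n_cells`).
#' @examples
#' pool <- taxon_pool(c("a", "b"), c(0.99, 0.01))
#' sample_inoculum(pool, n_cells = 1000, seed = 1)
#' @export
sample_inoculum <- function(pool, n_cells = 2e5, seed = NULL) {
  validate_taxon_pool(pool)
  assert_scalar_number(n_cells, "n_cells", min = 0, strict_min = TRUE)
  counts <- with_seed_or_global(
    seed,
    as.vector(rmultinom(1, size = n_cells, prob = pool$rel_abundance))
  )
  out <- tibble(taxon_id = pool$taxon_id, count = counts)
  class(out) <- c("inoculum", class(out))
  out
}

align_counts <- function(inoc, pool) {
  assert_that(is.data.frame(inoc) &&
                all(c("taxon_id", "count") %in% names(inoc)),
              "`inoc` must have columns `taxon_id` and `count`.")
  assert_that(all(inoc$count >= 0), "`count` values must be non-negative.")
  idx <- match(pool$taxon_id, inoc$taxon_id)
  assert_that(!anyNA(idx) && nrow(inoc) == nrow(pool),
              "`inoc` taxa must match the pool exactly.")
  inoc$count[idx]
}

#' Simulate one carbon-limited batch growth phase
#'
#' Integrates the shared-substrate Monod competition system
#' \deqn{dN_i/dt = \mu_i S/(K_s + S) N_i, \qquad
#'       dS/dt = -(c_{cell}/Y) \sum_i dN_i/dt}
#' from the inoculum until the substrate is depleted (below
#' `tol_S * S0`), with no death, lag or interaction terms. Growth is
#' deterministic; all stochasticity in the workflow enters through
#' [sample_inoculum()] and [subsample_counts()]. Taxa inoculated at zero
#' cells remain at zero. Because every batch runs to carbon depletion, the
#' final *total* community size is stoichiometric
#' (`N0 + Y * S0 / c_cell`) and independent of the kinetic parameters,
#' which only shape the final *composition*.
#'
#' @param inoc An [sample_inoculum()] result (or any tibble with
#'   `taxon_id`, `count` aligned to the pool).
#' @param pool A [taxon_pool()] with all growth rates assigned.
#' @param params A [growth_params()].
#' @param tol_S Relative substrate-depletion threshold. Default `1e-6`.
#' @param t_max Hard cap on simulated time (h). Default `1e4`.
#' @return An object of class `batch_sim`: a list with `state` (tibble of
#'   `taxon_id`, `growth_rate`, `n0`, `n_final`), `substrate` (g C left),
#'   `time` (h elapsed), `params`, and `mass_balance_error` (relative).
#' @examples
#' pool <- taxon_pool("a", 1, growth_rate = 0.4)
#' inoc <- sample_inoculum(pool, 2e5, seed = 1)
#' sim <- simulate_batch(inoc, pool, growth_params())
#' glance(sim)
#' @export
simulate_batch <- function(inoc, pool, params, tol_S = 1e-6, t_max = 1e4) {
  validate_taxon_pool(pool)
  validate_growth_params(params)
  n0 <- align_counts(inoc, pool)
  assert_that(all(!is.na(pool$growth_rate)),
              "All pool growth rates must be assigned before simulation.")

  state <- tibble(taxon_id = pool$taxon_id,
                  growth_rate = pool$growth_rate,
                  n0 = as.numeric(n0), n_final = as.numeric(n0))
  finish <- function(n_final, substrate, time) {
    state$n_final <- n_final
    consumed <- params$S0 - substrate
    expected <- (sum(n_final) - sum(n0)) * params$c_cell / params$Y
    mbe <- if (consumed > 0) abs(expected - consumed) / consumed else 0
    structure(list(state = state, substrate = substrate, time = time,
                   params = params, mass_balance_error = mbe),
              class = "batch_sim")
  }

  active <- n0 > 0
  if (params$S0 == 0 || !any(active)) {
    return(finish(as.numeric(n0), params$S0, 0))
  }

  mu <- pool$growth_rate[active]
  cc_over_Y <- params$c_cell / params$Y
  K_s <- params$K_s
  deriv <- function(t, y, p) {
    S <- max(y[length(y)], 0)
    dN <- mu * S / (K_s + S) * y[-length(y)]
    list(c(dN, -cc_over_Y * sum(dN)))
  }
  S_stop <- tol_S * params$S0
  rootfun <- function(t, y, p) y[length(y)] - S_stop
  y0 <- c(as.numeric(n0[active]), params$S0)
  sol <- deSolve::lsodar(y0, times = c(0, t_max), func = deriv,
                         parms = NULL, rootfunc = rootfun,
                         rtol = 1e-8, atol = c(rep(1e-6, sum(active)), 1e-18))
  last <- sol[nrow(sol), -1]
  if (any(!is.finite(last))) {
    abort("Non-finite state encountered during batch integration.")
  }
  n_final <- as.numeric(n0)
  n_final[active] <- pmax(as.numeric(last[seq_len(sum(active))]), n0[active])
  finish(n_final, max(as.numeric(last[sum(active) + 1]), 0),
         as.numeric(sol[nrow(sol), 1]))
}

#' Subsample a community as if sequencing
#'
#' Draws `depth` reads multinomially with probabilities proportional to the
#' final cell counts, emulating the sampling noise of an amplicon library
#' of `depth` reads.
#'
#' @param state A `batch_sim` object or a tibble with `taxon_id` and a
#'   count column (`n_final` or `count`).
#' @param depth Number of reads to draw. Default `2e5`. Must not exceed the
#'   community size.
#' @param seed Optional integer seed.
#' @return A tibble of class `inoculum` with `taxon_id`, `count`
#'   (integers summing to `depth`).
#' @export
subsample_counts <- function(state, depth = 2e5, seed = NULL) {
  tbl <- community_counts(state)
  assert_scalar_number(depth, "depth", min = 0, strict_min = TRUE)
  total <- sum(tbl$count)
  if (depth > total) {
    abort(sprintf("`depth` (%g) exceeds the community size (%g).",
                  depth, total))
  }
  counts <- with_seed_or_global(
    seed, as.vector(rmultinom(1, size = depth, prob = tbl$count))
  )
  out <- tibble(taxon_id = tbl$taxon_id, count = counts)
  class(out) <- c("inoculum", class(out))
  out
}

# Coerce a batch_sim or count table to tibble(taxon_id, count).
community_counts <- function(state) {
  if (inherits(state, "batch_sim")) {
    return(tibble(taxon_id = state$state$taxon_id,
                  count = state$state$n_final))
  }
  assert_that(is.data.frame(state) && "taxon_id" %in% names(state),
              "`state` must be a batch_sim or a taxon_id/count table.")
  cnt <- if ("count" %in% names(state)) state$count else state$n_final
  assert_that(!is.null(cnt) && all(cnt >= 0),
              "`state` must carry non-negative counts.")
  tibble(taxon_id = state$taxon_id, count = as.numeric(cnt))
}

#' Run an ensemble of independent replicate simulations
#'
#' Each replicate performs the full stochastic protocol: sample a finite
#' inoculum from the pool, grow it to carbon depletion, then subsample the
#' final community to sequencing depth. Replicates differ only through
#' their seeds; the divergence of their final compositions quantifies the
#' inoculum-bottleneck effect.
#'
#' @inheritParams simulate_batch
#' @param n_replicates Number of replicates. Default 5.
#' @param n_cells Inoculum size per replicate. Default `2e5`.
#' @param depth Sequencing subsample depth. Default `2e5`.
#' @param seeds Integer vector of per-replicate seeds (length
#'   `n_replicates`), or a single root seed from which per-replicate seeds
#'   are derived deterministically.
#' @return An object of class `sim_ensemble`: a list with `results` (long
#'   tibble: `replicate`, `taxon_id`, `focal`, `growth_rate`,
#'   `inoc_count`, `final_count`, `reads`, `rel_abundance`), `seeds`, and
#'   `totals` (per-replicate final sizes).
#' @examples
#' pool <- assign_growth_rates(taxon_pool(c("a", "b"), c(0.9, 0.1)))
#' ens <- run_replicate_ensemble(pool, growth_params(), n_replicates = 2,
#'                               n_cells = 1000, depth = 1000, seeds = 7)
#' tidy(ens)
#' @export
run_replicate_ensemble <- function(pool, params, n_replicates = 5,
                                   n_cells = 2e5, depth = 2e5,
                                   seeds = NULL) {
  validate_taxon_pool(pool)
  validate_growth_params(params)
  assert_scalar_number(n_replicates, "n_replicates", min = 1)
  if (is.null(seeds)) {
    seeds <- derive_seeds(NULL, n_replicates)
  } else if (length(seeds) == 1L && n_replicates > 1L) {
    seeds <- derive_seeds(seeds, n_replicates)
  }
  assert_that(length(seeds) == n_replicates,
              "`seeds` must supply one seed per replicate.")

  one <- function(r) {
    s <- derive_seeds(seeds[r], 2)
    inoc <- sample_inoculum(pool, n_cells = n_cells, seed = s[1])
    sim <- simulate_batch(inoc, pool, params)
    read_counts <- subsample_counts(sim, depth = depth, seed = s[2])$count
    tibble(replicate = r,
           taxon_id = pool$taxon_id,
           focal = pool$focal,
           growth_rate = pool$growth_rate,
           inoc_count = inoc$count,
           final_count = sim$state$n_final,
           reads = read_counts,
           rel_abundance = read_counts / sum(read_counts))
  }
  results <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    tryCatch(one(r), error = function(e) {
      abort(sprintf("Replicate %d failed: %s", r, conditionMessage(e)))
    })
  })
  totals <- results |>
    group_by(.data$replicate) |>
    summarise(final_size = sum(.data$final_count), .groups = "drop")
  structure(list(results = results, seeds = as.integer(seeds),
                 totals = totals, params = params),
            class = "sim_ensemble")
}

#' Cast ensemble reads to a samples-by-taxa community matrix
#'
#' @param ensemble A `sim_ensemble` (or `cycle_trajectory`) object.
#' @param value Column to spread: `"reads"` (default), `"rel_abundance"`
#'   or `"final_count"`.
#' @return A tibble with `sample_id` plus one column per taxon, suitable
#'   for [normalize_depth()] and [centroid_distances()].
#' @export
community_matrix <- function(ensemble, value = "reads") {
  res <- if (is.data.frame(ensemble)) ensemble else ensemble$results
  assert_that(value %in% names(res),
              paste0("Column `", value, "` not found in the results."))
  keys <- intersect(c("replicate", "cycle"), names(res))
  res$sample_id <- do.call(paste, c(unname(res[keys]), sep = "_"))
  res |>
    select(all_of(c("sample_id", keys, "taxon_id", value))) |>
    tidyr::pivot_wider(names_from = "taxon_id", values_from = all_of(value),
                       values_fill = 0)
}
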