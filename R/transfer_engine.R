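#' Configuration of a serial growth/dilution regime
#'
#' Describes the weekly transfer experiment: repeated batch growth to
#' carbon depletion followed by a 1:10 transfer into fresh sterile matrix
#' with fresh substrate.
#'
#' @param n_cycles Number of growth/dilution cycles. Default 8.
#' @param dilution_factor Fold dilution at each transfer (> 1). Default 10.
#' @param fresh_S0 Fresh substrate carbon added per cycle (g C). Default
#'   `2e-4`, matching [growth_params()].
#' @param sampling_depth Reads drawn per per-cycle sample. Default `2e5`.
#' @param seeds Optional per-cycle seeds (length `n_cycles`), or a single
#'   root seed.
#' @return A list of class `regime_config`.
#' @export
regime_config <- function(n_cycles = 8, dilution_factor = 10,
                          fresh_S0 = 2e-4, sampling_depth = 2e5,
                          seeds = NULL) {
  assert_scalar_number(n_cycles, "n_cycles", min = 1)
  assert_scalar_number(dilution_factor, "dilution_factor", min = 1,
                       strict_min = TRUE)
  assert_scalar_number(fresh_S0, "fresh_S0", min = 0)
  assert_scalar_number(sampling_depth, "sampling_depth", min = 1)
  if (!is.null(seeds) && length(seeds) == 1L && n_cycles > 1L) {
    seeds <- derive_seeds(seeds, n_cycles)
  }
  if (!is.null(seeds)) {
    assert_that(length(seeds) == n_cycles,
                "`seeds` must supply one seed per cycle.")
  }
  structure(list(n_cycles = as.integer(n_cycles),
                 dilution_factor = dilution_factor,
                 fresh_S0 = fresh_S0,
                 sampling_depth = sampling_depth,
                 seeds = seeds),
            class = "regime_config")
}

#' Dilute a community by stochastic bottleneck
#'
#' Transfers a community into fresh matrix by thinning each taxon's cell
#' count binomially with retention probability `1/factor` — each cell is
#' independently carried over or left behind. This, rather than exact
#' division, is what makes serial transfers a repeated bottleneck for rare
#' taxa.
#'
#' @param state A `batch_sim` object or taxon_id/count table.
#' @param factor Dilution factor (> 1). Default 10.
#' @param seed Optional integer seed.
#' @return A tibble of class `inoculum` with integer `count`.
#' @examples
#' dilute(tibble::tibble(taxon_id = "a", count = 1e6), factor = 10, seed = 1)
#' @export
dilute <- function(state, factor = 10, seed = NULL) {
  tbl <- community_counts(state)
  assert_scalar_number(factor, "factor", min = 1, strict_min = TRUE)
  counts <- with_seed_or_global(
    seed, rbinom(nrow(tbl), size = round(tbl$count), prob = 1 / factor)
  )
  out <- tibble(taxon_id = tbl$taxon_id, count = counts)
  class(out) <- c("inoculum", class(out))
  out
}

#' Propagate a community through serial growth/dilution cycles
#'
#' Runs the transfer regime in silico: per cycle, grow the current
#' inoculum to substrate depletion ([simulate_batch()]), record a
#' sequencing-depth subsample, then thin 1:`dilution_factor` into the next
#' cycle ([dilute()]). Unconsumed substrate carries over and adds to the
#' next cycle's fresh pool. If the community goes extinct at a transfer,
#' the trajectory is truncated and flagged.
#'
#' @param inoc Starting inoculum (tibble `taxon_id`, `count`).
#' @param pool A [taxon_pool()] with rates assigned.
#' @param params A [growth_params()]; its `S0` is used for the first cycle,
#'   subsequent cycles use `regime$fresh_S0` plus carry-over.
#' @param regime A [regime_config()].
#' @return An object of class `cycle_trajectory`: list with `results`
#'   (long tibble: `cycle`, `taxon_id`, `count`, `reads`,
#'   `rel_abundance`), `totals` (per-cycle final sizes), and `extinct`
#'   (logical).
#' @export
run_cycles <- function(inoc, pool, params, regime = regime_config()) {
  validate_taxon_pool(pool)
  validate_growth_params(params)
  assert_that(inherits(regime, "regime_config"),
              "`regime` must be created with `regime_config()`.")
  seeds <- regime$seeds %||% derive_seeds(NULL, regime$n_cycles)

  current <- tibble(taxon_id = pool$taxon_id,
                    count = align_counts(inoc, pool))
  S0 <- params$S0
  rows <- list()
  totals <- numeric(0)
  extinct <- FALSE
  for (cy in seq_len(regime$n_cycles)) {
    if (sum(current$count) == 0) {
      extinct <- TRUE
      break
    }
    s <- derive_seeds(seeds[cy], 2)
    p <- growth_params(S0 = S0, K_s = params$K_s, Y = params$Y,
                       c_cell = params$c_cell)
    sim <- simulate_batch(current, pool, p)
    depth <- min(regime$sampling_depth, sum(sim$state$n_final))
    read_counts <- subsample_counts(sim, depth = depth, seed = s[1])$count
    rows[[cy]] <- tibble(cycle = cy,
                         taxon_id = pool$taxon_id,
                         count = sim$state$n_final,
                         reads = read_counts,
                         rel_abundance = read_counts / sum(read_counts))
    totals[cy] <- sum(sim$state$n_final)
    current <- dilute(sim, factor = regime$dilution_factor, seed = s[2])
    # unconsumed carbon is transferred alongside the cells
    S0 <- regime$fresh_S0 + sim$substrate / regime$dilution_factor
  }
  if (length(rows) == 0) {
    abort("Starting inoculum is empty; nothing to propagate.")
  }
  structure(list(results = bind_rows(rows),
                 totals = tibble(cycle = seq_along(totals),
                                 final_size = totals),
                 extinct = extinct,
                 seeds = as.integer(seeds)),
            class = "cycle_trajectory")
}
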