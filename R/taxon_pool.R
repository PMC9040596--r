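#' Construct a taxon pool
#'
#' A taxon pool describes the modelled species pool of a soil community:
#' taxon identifiers, relative abundances, maximum specific growth rates and
#' a flag marking "focal" taxa (rare taxa whose growth rate is set by hand
#' rather than by the abundance map).
#'
#' @param taxon_id Character vector of unique taxon identifiers.
#' @param rel_abundance Numeric vector of relative abundances; must be
#'   non-negative and sum to 1 (within `1e-9`).
#' @param growth_rate Numeric vector of maximum specific growth rates
#'   (h^-1), or `NA` if not yet assigned. Non-`NA` values must be positive
#'   and finite.
#' @param focal Logical vector marking focal taxa. Default all `FALSE`.
#'
#' @return A tibble of class `taxon_pool` with columns `taxon_id`,
#'   `rel_abundance`, `growth_rate`, `focal`.
#' @examples
#' taxon_pool(c("t1", "t2"), c(0.9, 0.1), growth_rate = c(0.4, 0.1))
#' @export
taxon_pool <- function(taxon_id, rel_abundance, growth_rate = NA_real_,
                       focal = FALSE) {
  taxon_id <- as.character(taxon_id)
  assert_that(!anyDuplicated(taxon_id) && !anyNA(taxon_id),
              "`taxon_id` entries must be unique and non-missing.")
  assert_that(is.numeric(rel_abundance) &&
                length(rel_abundance) == length(taxon_id),
              "`rel_abundance` must be numeric, one value per taxon.")
  assert_that(all(rel_abundance >= 0),
              "`rel_abundance` entries must be non-negative.")
  assert_that(abs(sum(rel_abundance) - 1) <= 1e-9,
              "`rel_abundance` must sum to 1 (within 1e-9).")
  growth_rate <- rep_len(as.numeric(growth_rate), length(taxon_id))
  ok <- is.na(growth_rate) | (is.finite(growth_rate) & growth_rate > 0)
  assert_that(all(ok), "`growth_rate` values must be positive and finite.")
  focal <- rep_len(as.logical(focal), length(taxon_id))
  out <- tibble(taxon_id = taxon_id, rel_abundance = rel_abundance,
                growth_rate = growth_rate, focal = focal)
  class(out) <- c("taxon_pool", class(out))
  out
}

validate_taxon_pool <- function(pool) {
  assert_that(is.data.frame(pool) &&
                all(c("taxon_id", "rel_abundance", "growth_rate",
                      "focal") %in% names(pool)),
              "`pool` must be a taxon_pool (see `taxon_pool()`).")
  invisible(pool)
}

#' Assign growth rates from the rank-abundance distribution
#'
#' Maps each non-focal taxon's maximum growth rate linearly in log10
#' relative abundance: the most abundant taxon receives `mu_max`, the
#' rarest `mu_min`. This encodes the modelling assumption that taxa
#' abundant in the source soil are the fastest opportunistic growers under
#' the microcosm's nutrient regime. Focal taxa (see [set_focal_rates()])
#' keep their hand-set rates.
#'
#' If all abundances are equal (including a single-taxon pool) the log
#' range is degenerate and every taxon receives `mu_max`.
#'
#' @param pool A [taxon_pool()].
#' @param mu_min,mu_max Rate bounds in h^-1; `mu_min <= mu_max`. Defaults
#'   0.01 and 0.4.
#' @return The pool with `growth_rate` filled for non-focal taxa.
#' @examples
#' pool <- taxon_pool(c("a", "b", "c"), c(0.9, 0.09, 0.01))
#' assign_growth_rates(pool)$growth_rate
#' @export
assign_growth_rates <- function(pool, mu_min = 0.01, mu_max = 0.4) {
  validate_taxon_pool(pool)
  assert_scalar_number(mu_min, "mu_min", min = 0, strict_min = TRUE)
  assert_scalar_number(mu_max, "mu_max", min = mu_min)
  target <- !pool$focal
  assert_that(all(pool$rel_abundance[target] > 0),
              "All non-focal taxa must have rel_abundance > 0 to map rates.")
  la <- log10(pool$rel_abundance[target])
  rng <- diff(range(la))
  rate <- if (rng == 0 || mu_min == mu_max) {
    rep(mu_max, sum(target))
  } else {
    mu_min + (mu_max - mu_min) * (la - min(la)) / rng
  }
  pool$growth_rate[target] <- rate
  pool
}

#' Override growth rates of focal taxa
#'
#' Marks a set of taxa as focal and assigns them explicit growth rates,
#' typically rare taxa given fast rates to study inoculum subsampling
#' effects (default use: five rare taxa at 0.55, 0.25, 0.8, 0.6 and
#' 0.35 h^-1).
#'
#' @param pool A [taxon_pool()].
#' @param focal_ids Character vector of taxon ids present in `pool`
#'   (no duplicates).
#' @param rates Numeric vector of rates (h^-1), same length as `focal_ids`.
#' @return The pool with overrides applied and `focal` flags set.
#' @export
set_focal_rates <- function(pool, focal_ids, rates) {
  validate_taxon_pool(pool)
  if (length(focal_ids) == 0L) return(pool)
  focal_ids <- as.character(focal_ids)
  assert_that(!anyDuplicated(focal_ids), "`focal_ids` must be unique.")
  assert_that(length(rates) == length(focal_ids),
              "`rates` must have one value per focal id.")
  missing <- setdiff(focal_ids, pool$taxon_id)
  if (length(missing) > 0) {
    abort(paste0("Unknown taxon id(s): ", paste(missing, collapse = ", ")))
  }
  assert_that(all(is.finite(rates) & rates > 0),
              "`rates` must be positive and finite.")
  idx <- match(focal_ids, pool$taxon_id)
  pool$growth_rate[idx] <- as.numeric(rates)
  pool$focal[idx] <- TRUE
  pool
}

#' Read a taxon abundance table from TSV
#'
#' Expects at least the columns `taxon_id` and `rel_abundance`.
#'
#' @param path Path to a tab-separated file.
#' @return A [taxon_pool()].
#' @export
read_taxon_pool <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(all(c("taxon_id", "rel_abundance") %in% names(d)),
              "TSV must contain columns `taxon_id` and `rel_abundance`.")
  taxon_pool(d$taxon_id, d$rel_abundance,
             growth_rate = d$growth_rate %||% NA_real_,
             focal = d$focal %||% FALSE)
}
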