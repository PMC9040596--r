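# Back-of-the-envelope calculators for microcosm design and reporting:
# carbon-supported community size, inoculation density, growth fold/
# doublings, nominal solvent concentration, RockEval indices.

#' Physico-chemical constants for toluene
#'
#' Density (g mL^-1) and molar mass (g mol^-1) of toluene, used as
#' defaults by [nominal_concentration()].
#' @export
toluene_constants <- list(density_g_per_ml = 0.867, mw_g_per_mol = 92.14)

#' Carbon-supported community size
#'
#' How many cells a soil matrix can support given its total organic
#' carbon content, a biomass yield and a per-cell carbon quota:
#' `cells = toc * Y / c_cell`.
#'
#' @param toc_g_per_g Total organic carbon (g C per g soil). Default
#'   `1.5e-3` (1.5 mg C g^-1).
#' @param Y Carbon-to-biomass yield fraction. Default 0.2.
#' @param c_cell Carbon per cell (g). Default `2e-13` (200 fg).
#' @return A tibble with `cells_per_g` and `order_of_magnitude`
#'   (`floor(log10(cells))`).
#' @examples
#' carbon_budget() # ~1.5e9 cells/g, order 9
#' @export
carbon_budget <- function(toc_g_per_g = 1.5e-3, Y = 0.2, c_cell = 2e-13) {
  assert_scalar_number(toc_g_per_g, "toc_g_per_g", min = 0, strict_min = TRUE)
  assert_scalar_number(Y, "Y", min = 0, max = 1, strict_min = TRUE)
  assert_scalar_number(c_cell, "c_cell", min = 0, strict_min = TRUE)
  cells <- toc_g_per_g * Y / c_cell
  tibble(cells_per_g = cells, order_of_magnitude = floor(log10(cells)))
}

#' Inoculation density per gram of microcosm
#'
#' Cells delivered per gram of soil when inoculating `volume_ml` of a
#' suspension at `cells_per_ml` into `soil_mass_g` of matrix.
#'
#' @param volume_ml Inoculum volume (mL). Default 10.
#' @param cells_per_ml Suspension density (cells mL^-1). Default `1e7`.
#' @param soil_mass_g Soil mass (g). Default 100.
#' @return Cells per gram of soil.
#' @examples
#' inoculation_density() # 1e6
#' @export
inoculation_density <- function(volume_ml = 10, cells_per_ml = 1e7,
                                soil_mass_g = 100) {
  assert_scalar_number(volume_ml, "volume_ml", min = 0)
  assert_scalar_number(cells_per_ml, "cells_per_ml", min = 0)
  assert_scalar_number(soil_mass_g, "soil_mass_g", min = 0,
                       strict_min = TRUE)
  volume_ml * cells_per_ml / soil_mass_g
}

#' Fold increase and number of doublings
#'
#' @param n0 Starting density (> 0).
#' @param nt Final density (> 0).
#' @return A tibble with `fold` (`nt/n0`) and `doublings` (`log2(fold)`).
#' @examples
#' fold_and_doublings(1e6, 2.8e8) # 280-fold, ~8 doublings
#' @export
fold_and_doublings <- function(n0, nt) {
  assert_scalar_number(n0, "n0", min = 0, strict_min = TRUE)
  assert_scalar_number(nt, "nt", min = 0, strict_min = TRUE)
  fold <- nt / n0
  tibble(fold = fold, doublings = log2(fold))
}

#' Nominal concentration of a neat solvent spike
#'
#' Concentration (mM) a volume of pure solvent would reach if fully
#' dissolved in the system volume:
#' `mM = volume_ul * 1e-3 * density / mw / system_volume_l * 1e3`.
#'
#' @param volume_ul Spike volume (microliters).
#' @param system_volume_l Total system volume (L).
#' @param density_g_per_ml Solvent density. Default toluene (0.867).
#' @param mw_g_per_mol Solvent molar mass. Default toluene (92.14).
#' @return Nominal concentration in mM.
#' @examples
#' nominal_concentration(100, 0.5) # 1.88 mM toluene
#' @export
nominal_concentration <- function(volume_ul, system_volume_l,
                                  density_g_per_ml =
                                    toluene_constants$density_g_per_ml,
                                  mw_g_per_mol =
                                    toluene_constants$mw_g_per_mol) {
  assert_scalar_number(volume_ul, "volume_ul", min = 0)
  assert_scalar_number(system_volume_l, "system_volume_l", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(density_g_per_ml, "density_g_per_ml", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(mw_g_per_mol, "mw_g_per_mol", min = 0,
                       strict_min = TRUE)
  mol <- volume_ul * 1e-3 * density_g_per_ml / mw_g_per_mol
  mol / system_volume_l * 1e3
}

#' RockEval hydrogen and oxygen indices
#'
#' `HI = S2 / TOC * 100` and `OI = S3 / TOC * 100`, characterizing the
#' hydrogen and oxygen content of soil organic matter relative to total
#' organic carbon from RockEval pyrolysis peaks.
#'
#' @param S2 Pyrolyzable hydrocarbon peak (mg HC g^-1).
#' @param S3 CO2 peak (mg CO2 g^-1).
#' @param TOC Total organic carbon (same mass basis); must be > 0.
#' @return A tibble with `HI` and `OI`.
#' @examples
#' rockeval_indices(3, 1.5, 2) # HI 150, OI 75
#' @export
rockeval_indices <- function(S2, S3, TOC) {
  assert_scalar_number(S2, "S2", min = 0)
  assert_scalar_number(S3, "S3", min = 0)
  assert_scalar_number(TOC, "TOC", min = 0, strict_min = TRUE)
  tibble(HI = S2 / TOC * 100, OI = S3 / TOC * 100)
}
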