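#' Read a flow-cytometry event table from CSV
#'
#' Plain CSV export with one row per event and header columns `FSC-H`
#' (forward scatter height) and `FITC-H` (SYBR Green I fluorescence
#' height). No FCS parsing is attempted.
#'
#' @param path Path to the CSV file.
#' @return A tibble with at least columns `FSC-H` and `FITC-H`.
#' @export
read_fcm_events <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(all(c("FSC-H", "FITC-H") %in% names(d)),
              "Event CSV must contain columns `FSC-H` and `FITC-H`.")
  d
}

#' Gate flow-cytometry events on scatter and fluorescence thresholds
#'
#' Counts events considered to potentially originate from microbial cells:
#' those with forward scatter strictly above `fsc_min` and SYBR-green
#' fluorescence strictly above `fitc_min`. Defaults follow buffer-control
#' calibration (FSC-H > 50, FITC-H > 350).
#'
#' @param events A tibble with columns `FSC-H` and `FITC-H` (e.g. from
#'   [read_fcm_events()]).
#' @param fsc_min,fitc_min Gate thresholds (instrument units).
#' @return Integer count of gated events (0 for an empty table).
#' @examples
#' ev <- tibble::tibble(`FSC-H` = c(60, 60, 40), `FITC-H` = c(400, 300, 400))
#' gate_events(ev)
#' @export
gate_events <- function(events, fsc_min = 50, fitc_min = 350) {
  assert_that(is.data.frame(events) &&
                all(c("FSC-H", "FITC-H") %in% names(events)),
              "`events` must contain columns `FSC-H` and `FITC-H`.")
  # thresholds may be -Inf ("no gate"), so only NA is rejected
  assert_that(is.numeric(fsc_min) && length(fsc_min) == 1 && !is.na(fsc_min),
              "`fsc_min` must be a single number.")
  assert_that(is.numeric(fitc_min) && length(fitc_min) == 1 &&
                !is.na(fitc_min),
              "`fitc_min` must be a single number.")
  if (nrow(events) == 0) return(0L)
  fsc <- events[["FSC-H"]]
  fitc <- events[["FITC-H"]]
  assert_that(all(is.finite(fsc)) && all(is.finite(fitc)),
              "Event channel values must be finite.")
  sum(fsc > fsc_min & fitc > fitc_min)
}

#' Convert gated counts to a cell density
#'
#' Subtracts the gated count of the matched uninoculated blank (colloidal
#' background) from a sample's gated count, then scales by the acquisition
#' volume and the sample dilution factor. Subtraction happens on gated
#' counts at matched volume and dilution; a blank exceeding the sample is
#' clipped to zero density with a warning.
#'
#' @param gated Gated event count of the sample.
#' @param blank_gated Gated event count of the paired blank. Default 0.
#' @param volume_ul Acquisition volume in microliters. Default 20.
#' @param dilution Fold dilution of the sample before counting (>= 1).
#'   Default 1.
#' @return Cell density in cells mL^-1.
#' @examples
#' cells_per_ml(2000, 0, volume_ul = 20, dilution = 100) # 1e7
#' @export
cells_per_ml <- function(gated, blank_gated = 0, volume_ul = 20,
                         dilution = 1) {
  assert_scalar_number(gated, "gated", min = 0)
  assert_scalar_number(blank_gated, "blank_gated", min = 0)
  assert_scalar_number(volume_ul, "volume_ul", min = 0, strict_min = TRUE)
  assert_scalar_number(dilution, "dilution", min = 1)
  net <- gated - blank_gated
  if (net < 0) {
    warn("Blank gated count exceeds sample; density clipped to 0.")
    net <- 0
  }
  net / (volume_ul * 1e-3) * dilution
}

#' Compute densities for a sample sheet of event tables
#'
#' Convenience wrapper pairing each sample with its blank via a sample
#' sheet (`sample_id`, `blank_id`, `volume_ul`, `dilution`), gating both
#' and returning one density per sample.
#'
#' @param event_tables Named list of event tibbles; names must cover all
#'   `sample_id` and `blank_id` values (blanks may be `NA` for none).
#' @param sample_sheet Tibble with columns `sample_id`, `blank_id`,
#'   `volume_ul`, `dilution`.
#' @inheritParams gate_events
#' @return A tibble: `sample_id`, `gated`, `blank_gated`, `cells_per_ml`.
#' @export
fcm_densities <- function(event_tables, sample_sheet,
                          fsc_min = 50, fitc_min = 350) {
  need <- c("sample_id", "blank_id", "volume_ul", "dilution")
  assert_that(is.data.frame(sample_sheet) &&
                all(need %in% names(sample_sheet)),
              paste("`sample_sheet` must contain columns:",
                    paste(need, collapse = ", ")))
  purrr::pmap_dfr(sample_sheet[need], function(sample_id, blank_id,
                                               volume_ul, dilution) {
    assert_that(sample_id %in% names(event_tables),
                paste0("No event table for sample '", sample_id, "'."))
    g <- gate_events(event_tables[[sample_id]], fsc_min, fitc_min)
    b <- if (is.na(blank_id)) 0L else {
      assert_that(blank_id %in% names(event_tables),
                  paste0("No event table for blank '", blank_id, "'."))
      gate_events(event_tables[[blank_id]], fsc_min, fitc_min)
    }
    tibble(sample_id = sample_id, gated = g, blank_gated = b,
           cells_per_ml = cells_per_ml(g, b, volume_ul, dilution))
  })
}
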