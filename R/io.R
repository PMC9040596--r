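# Plain-text I/O for the tabular containers: community matrices and
# distance matrices as TSV, run metadata as JSON.

#' Write / read a community matrix as TSV
#'
#' @param m A community matrix tibble (see [community_matrix()]).
#' @param path File path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_community_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a square distance matrix as TSV
#'
#' @param d A square matrix (e.g. from [bc_distance_matrix()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  out <- as_tibble(d, rownames = "sample_id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records the configuration, seeds and package version of a run so the
#' run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seeds Integer seeds used.
#' @param outputs Character vector of file paths written by the run.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, config, seeds = NULL,
                               outputs = character()) {
  jsonlite::write_json(
    list(package = "soilcosm",
         version = as.character(packageVersion("soilcosm")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config,
         seeds = seeds,
         outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
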