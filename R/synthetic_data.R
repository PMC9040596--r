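# Seeded generators for the three kinds of synthetic inputs the analysis
# consumes: long-tailed rank-abundance pools, amplicon reads with embedded
# strain identifiers, and flow-cytometry event tables. Every generator is
# a pure function of its arguments and seed, and carries a machine-readable
# truth record for round-trip testing.

#' Generate a long-tailed soil rank-abundance pool
#'
#' Draws taxon abundances from a lognormal distribution, normalizes them
#' to sum to 1 and sorts descending — the classic few-dominants /
#' long-rare-tail shape of soil communities. Default 314 taxa with
#' `sdlog = 2`, which puts well over half of the taxa below 1e-3 relative
#' abundance.
#'
#' @param n_taxa Number of taxa. Default 314.
#' @param meanlog,sdlog Lognormal parameters of the raw abundances.
#'   Defaults 0 and 2. `sdlog = 0` yields a uniform pool.
#' @param seed Optional integer seed.
#' @return A [taxon_pool()] sorted by decreasing abundance, with taxa
#'   named `t1..tn` (t1 most abundant) and attributes `rank1_share` and
#'   `tail_share` (fraction of taxa below 1e-3).
#' @examples
#' pool <- make_rank_abundance(n_taxa = 50, seed = 1)
#' attr(pool, "rank1_share")
#' @export
make_rank_abundance <- function(n_taxa = 314, meanlog = 0, sdlog = 2,
                                seed = NULL) {
  assert_scalar_number(n_taxa, "n_taxa", min = 1)
  assert_scalar_number(sdlog, "sdlog", min = 0)
  raw <- with_seed_or_global(seed, rlnorm(n_taxa, meanlog, sdlog))
  ab <- sort(raw / sum(raw), decreasing = TRUE)
  pool <- taxon_pool(paste0("t", seq_len(n_taxa)), ab)
  attr(pool, "rank1_share") <- ab[1]
  attr(pool, "tail_share") <- mean(ab < 1e-3)
  pool
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Generate a random strain identifier catalog
#'
#' Random identifier sequences of the requested lengths, re-drawn until
#' mutually non-substring, with operon copy numbers cycling through
#' `copies`.
#'
#' @param n_strains Number of strains.
#' @param lengths Identifier lengths to cycle through. Default `c(60, 90)`.
#' @param copies Operon copy numbers to cycle through. Default `1:7`.
#' @param seed Optional integer seed.
#' @return An [identifier_catalog()] with strains `S01..`.
#' @export
make_identifier_catalog <- function(n_strains = 21, lengths = c(60, 90),
                                    copies = 1:7, seed = NULL) {
  assert_scalar_number(n_strains, "n_strains", min = 1)
  with_seed_or_global(seed, {
    lens <- rep_len(lengths, n_strains)
    seqs <- character(n_strains)
    for (i in seq_len(n_strains)) {
      repeat {
        cand <- random_dna(1, lens[i])
        prev <- seqs[seq_len(i - 1)]
        clash <- length(prev) > 0 &&
          (any(vapply(prev, grepl, logical(1), x = cand, fixed = TRUE)) ||
             any(grepl(cand, prev, fixed = TRUE)))
        if (!clash) break
      }
      seqs[i] <- cand
    }
    identifier_catalog(sprintf("S%02d", seq_len(n_strains)), seqs,
                       rep_len(copies, n_strains), lengths = lengths)
  })
}

#' Generate amplicon reads embedding strain identifiers
#'
#' Each read is a random background sequence with exactly one strain's
#' identifier substituted in at a random offset; the strain is drawn
#' multinomially from `proportions`. Background segments are rejection-
#' sampled so that no read accidentally contains a second catalog
#' identifier. Reads are error-free: counting is exact-match by design.
#'
#' @param catalog An [identifier_catalog()].
#' @param proportions Named numeric vector of per-strain proportions
#'   (names in `catalog$strain_id`), summing to 1.
#' @param n_reads Number of reads.
#' @param read_length Read length (nt); at least the longest identifier.
#' @param seed Optional integer seed.
#' @param fastq Optional path; when given, reads are written there as
#'   FASTQ and a JSON truth file (`<path>.truth.json`) alongside.
#' @return A list with `reads` (`DNAStringSet`, named `read1..`), `truth`
#'   (tibble `strain_id`, `embedded_count`) and `fastq` (path or `NULL`).
#' @export
make_reads <- function(catalog, proportions, n_reads, read_length = 150,
                       seed = NULL, fastq = NULL) {
  assert_that(inherits(catalog, "identifier_catalog"),
              "`catalog` must be an identifier_catalog.")
  assert_that(!is.null(names(proportions)) &&
                all(names(proportions) %in% catalog$strain_id),
              "`proportions` must be named by catalog strain ids.")
  assert_that(abs(sum(proportions) - 1) <= 1e-9,
              "`proportions` must sum to 1.")
  maxlen <- max(nchar(catalog$identifier_seq))
  if (read_length < maxlen) {
    abort("`read_length` must be at least the longest identifier.")
  }
  assert_scalar_number(n_reads, "n_reads", min = 1)

  out <- with_seed_or_global(seed, {
    strains <- sample(names(proportions), n_reads, replace = TRUE,
                      prob = proportions)
    ids <- setNames(catalog$identifier_seq, catalog$strain_id)
    seqs <- vapply(strains, function(st) {
      id <- ids[[st]]
      repeat {
        bg <- random_dna(1, read_length)
        off <- sample.int(read_length - nchar(id) + 1, 1)
        read <- paste0(substr(bg, 1, off - 1), id,
                       substr(bg, off + nchar(id), read_length))
        # a background segment must not recreate any catalog identifier
        hits <- vapply(ids, grepl, logical(1), x = read, fixed = TRUE)
        if (sum(hits) == 1) return(read)
      }
    }, character(1))
    list(strains = strains, seqs = seqs)
  })
  reads <- Biostrings::DNAStringSet(out$seqs)
  names(reads) <- paste0("read", seq_len(n_reads))
  truth <- tibble(strain_id = catalog$strain_id) |>
    left_join(tibble(strain_id = out$strains) |>
                dplyr::count(.data$strain_id, name = "embedded_count"),
              by = "strain_id") |>
    mutate(embedded_count = tidyr::replace_na(.data$embedded_count, 0L))
  if (!is.null(fastq)) {
    Biostrings::writeXStringSet(reads, fastq, format = "fastq")
    jsonlite::write_json(
      list(n_reads = n_reads, read_length = read_length,
           truth = truth),
      paste0(fastq, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(reads = reads, truth = truth, fastq = fastq)
}

#' Generate a flow-cytometry event table with cell and background clouds
#'
#' Simulates `n_cells` cell-like events and `n_background` colloidal
#' background events as bivariate normal clouds on the FSC-H / FITC-H
#' channels. With the default means the two clouds sit strictly on
#' opposite sides of the standard gate (FSC-H > 50, FITC-H > 350); the
#' expected misclassification rates under the normal model are recorded
#' in the truth attribute.
#'
#' @param n_cells,n_background Event counts. Defaults 1000 and 500.
#' @param cell_means,cell_sds Channel means/SDs (FSC-H, FITC-H) of cells.
#'   Defaults `c(200, 1200)` and `c(30, 150)`.
#' @param bg_means,bg_sds Same for background. Defaults `c(30, 150)` and
#'   `c(8, 40)`.
#' @param seed Optional integer seed.
#' @param csv Optional path to also write the events as CSV.
#' @return A tibble with columns `FSC-H`, `FITC-H`, `population`
#'   (`"cell"`/`"background"`), and attribute `truth` (a list with the
#'   generating parameters and expected gate misclassification
#'   probabilities at the default thresholds).
#' @export
make_fcm_events <- function(n_cells = 1000, n_background = 500,
                            cell_means = c(200, 1200),
                            cell_sds = c(30, 150),
                            bg_means = c(30, 150), bg_sds = c(8, 40),
                            seed = NULL, csv = NULL) {
  assert_scalar_number(n_cells, "n_cells", min = 0)
  assert_scalar_number(n_background, "n_background", min = 0)
  ev <- with_seed_or_global(seed, {
    tibble(
      `FSC-H` = c(rnorm(n_cells, cell_means[1], cell_sds[1]),
                  rnorm(n_background, bg_means[1], bg_sds[1])),
      `FITC-H` = c(rnorm(n_cells, cell_means[2], cell_sds[2]),
                   rnorm(n_background, bg_means[2], bg_sds[2])),
      population = rep(c("cell", "background"),
                       c(n_cells, n_background))
    )
  })
  # expected misclassification under the generating normal model
  p_cell_out <- 1 - (1 - pnorm(50, cell_means[1], cell_sds[1])) *
    (1 - pnorm(350, cell_means[2], cell_sds[2]))
  p_bg_in <- (1 - pnorm(50, bg_means[1], bg_sds[1])) *
    (1 - pnorm(350, bg_means[2], bg_sds[2]))
  attr(ev, "truth") <- list(
    n_cells = n_cells, n_background = n_background,
    cell_means = cell_means, cell_sds = cell_sds,
    bg_means = bg_means, bg_sds = bg_sds,
    p_cell_missed = p_cell_out, p_background_gated = p_bg_in,
    overlapping = p_cell_out > 1e-6 || p_bg_in > 1e-6
  )
  if (!is.null(csv)) {
    readr::write_csv(ev, csv)
  }
  ev
}
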