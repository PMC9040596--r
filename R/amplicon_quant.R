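#' Construct a strain identifier catalog
#'
#' Each community strain is quantified by an identifier: a short unique
#' stretch of its 16S rRNA gene variable region (60 or 90 nt by default)
#' that occurs in no other member's gene. Counts of reads containing each
#' identifier are later corrected by the strain's 16S rRNA operon copy
#' number so that they reflect cells rather than gene copies.
#'
#' @param strain_id Character vector of unique strain names.
#' @param identifier_seq Character vector of DNA identifiers (A/C/G/T
#'   only). No identifier may be a substring of another (forward strand).
#' @param operon_copies Positive integer vector of 16S operon copy
#'   numbers per genome.
#' @param lengths Allowed identifier lengths. Default `c(60, 90)`; set
#'   `NULL` to accept any length.
#' @return A tibble of class `identifier_catalog`.
#' @export
identifier_catalog <- function(strain_id, identifier_seq, operon_copies,
                               lengths = c(60, 90)) {
  strain_id <- as.character(strain_id)
  identifier_seq <- toupper(as.character(identifier_seq))
  assert_that(!anyDuplicated(strain_id) && length(strain_id) > 0,
              "`strain_id` entries must be unique and non-empty.")
  assert_that(length(identifier_seq) == length(strain_id) &&
                length(operon_copies) == length(strain_id),
              "All catalog columns must have one entry per strain.")
  assert_that(all(grepl("^[ACGT]+$", identifier_seq)),
              "Identifiers must be non-empty A/C/G/T strings.")
  if (!is.null(lengths)) {
    assert_that(all(nchar(identifier_seq) %in% lengths),
                paste0("Identifier lengths must be in {",
                       paste(lengths, collapse = ", "), "}."))
  }
  assert_that(all(operon_copies == round(operon_copies) &
                    operon_copies >= 1),
              "`operon_copies` must be positive integers.")
  for (i in seq_along(identifier_seq)) {
    hits <- grepl(identifier_seq[i], identifier_seq[-i], fixed = TRUE)
    if (any(hits)) {
      abort(sprintf(
        "Identifier of strain '%s' is contained in another identifier.",
        strain_id[i]))
    }
  }
  out <- tibble(strain_id = strain_id, identifier_seq = identifier_seq,
                operon_copies = as.integer(operon_copies))
  class(out) <- c("identifier_catalog", class(out))
  out
}

#' Read an identifier catalog from FASTA + TSV
#'
#' @param fasta_path FASTA of identifier sequences, names = strain ids.
#' @param copies_path TSV with columns `strain_id`, `operon_copies`.
#' @inheritParams identifier_catalog
#' @return An [identifier_catalog()].
#' @export
read_identifier_catalog <- function(fasta_path, copies_path,
                                    lengths = c(60, 90)) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  copies <- readr::read_tsv(copies_path, show_col_types = FALSE)
  assert_that(all(c("strain_id", "operon_copies") %in% names(copies)),
              "Copies TSV must contain `strain_id` and `operon_copies`.")
  ids <- names(seqs)
  idx <- match(ids, copies$strain_id)
  assert_that(!anyNA(idx), "Every FASTA strain needs an operon-copy entry.")
  identifier_catalog(ids, as.character(seqs), copies$operon_copies[idx],
                     lengths = lengths)
}

read_reads <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
    return(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  Biostrings::DNAStringSet(toupper(as.character(reads)))
}

#' Count strain identifiers in amplicon reads
#'
#' Classifies each read by exact forward-strand substring search for every
#' catalog identifier (the programmatic equivalent of grep-counting
#' oriented merged reads against a reference list). Each read is counted
#' at most once; reads matching two or more identifiers are ambiguous and
#' excluded from all counts (their number is reported and logged).
#'
#' @param reads A `DNAStringSet`, character vector of sequences, or path
#'   to a FASTA/FASTQ file (gzip allowed).
#' @param catalog An [identifier_catalog()].
#' @param revcomp Also search the reverse complement of each identifier?
#'   Default `FALSE` (reads are assumed oriented).
#' @return A tibble with `strain_id`, `raw_count`, plus attributes
#'   `n_reads`, `n_ambiguous`, `n_unclassified`.
#' @export
count_identifiers <- function(reads, catalog, revcomp = FALSE) {
  assert_that(inherits(catalog, "identifier_catalog"),
              "`catalog` must be an identifier_catalog.")
  assert_that(nrow(catalog) > 0, "`catalog` must not be empty.")
  seqs <- read_reads(reads)
  hit <- vapply(catalog$identifier_seq, function(id) {
    h <- Biostrings::vcountPattern(id, seqs, fixed = TRUE) > 0
    if (revcomp) {
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(id)))
      h <- h | Biostrings::vcountPattern(rc, seqs, fixed = TRUE) > 0
    }
    h
  }, logical(length(seqs)))
  if (length(seqs) == 1L) hit <- matrix(hit, nrow = 1)
  n_match <- rowSums(hit)
  ambiguous <- n_match >= 2
  counts <- colSums(hit[!ambiguous, , drop = FALSE])
  if (any(ambiguous)) {
    inform(sprintf(
      "%d read(s) matched multiple identifiers and were excluded.",
      sum(ambiguous)))
  }
  out <- tibble(strain_id = catalog$strain_id,
                raw_count = as.integer(counts))
  attr(out, "n_reads") <- length(seqs)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "n_unclassified") <- sum(n_match == 0)
  out
}

#' Correct identifier counts for operon copy number and normalize
#'
#' Divides each strain's raw read count by its 16S rRNA operon copy
#' number (so counts reflect cells, not gene copies) and renormalizes to
#' relative abundances over the corrected counts.
#'
#' @param raw A tibble with `strain_id`, `raw_count` (e.g. from
#'   [count_identifiers()]), or a named numeric vector.
#' @param catalog An [identifier_catalog()].
#' @param n_classified Total classified reads in the sample; defaults to
#'   the sum of raw counts. Must be at least that sum.
#' @return A tibble of class `strain_count_table` with `strain_id`,
#'   `raw_count`, `corrected_count`, `rel_abundance` and attribute
#'   `n_classified`. If all raw counts are zero the table is returned with
#'   `rel_abundance` `NA` and attribute `empty_community = TRUE`.
#' @examples
#' cat21 <- identifier_catalog(c("A", "B"),
#'                             c(strrep("ACGT", 15), strrep("GGCA", 15)),
#'                             c(4, 2))
#' correct_and_normalize(c(A = 100, B = 100), cat21)
#' @export
correct_and_normalize <- function(raw, catalog, n_classified = NULL) {
  assert_that(inherits(catalog, "identifier_catalog"),
              "`catalog` must be an identifier_catalog.")
  if (!is.data.frame(raw)) {
    raw <- tibble(strain_id = names(raw), raw_count = as.numeric(raw))
  }
  assert_that(all(c("strain_id", "raw_count") %in% names(raw)),
              "`raw` must have columns `strain_id` and `raw_count`.")
  idx <- match(catalog$strain_id, raw$strain_id)
  assert_that(!anyNA(idx), "`raw` must cover every catalog strain.")
  raw_count <- raw$raw_count[idx]
  assert_that(all(raw_count >= 0), "Raw counts must be non-negative.")
  n_classified <- n_classified %||% sum(raw_count)
  assert_that(n_classified >= sum(raw_count),
              "`n_classified` cannot be below the sum of raw counts.")
  corrected <- raw_count / catalog$operon_copies
  total <- sum(corrected)
  empty <- total == 0
  out <- tibble(strain_id = catalog$strain_id,
                raw_count = raw_count,
                corrected_count = corrected,
                rel_abundance = if (empty) NA_real_ else corrected / total)
  class(out) <- c("strain_count_table", class(out))
  attr(out, "n_classified") <- n_classified
  attr(out, "empty_community") <- empty
  if (empty) warn("All raw counts are zero: empty-community state returned.")
  out
}

#' Anchor relative abundances to an absolute community size
#'
#' Converts relative sequence abundances to absolute per-strain densities
#' by multiplying with a total community size measured independently by
#' flow cytometry.
#'
#' @param table A `strain_count_table` from [correct_and_normalize()] (or
#'   any tibble with `strain_id` and `rel_abundance`).
#' @param total_cells_per_ml Total community density (cells mL^-1 or
#'   cells g^-1); must be non-negative.
#' @return The table with an added `abs_abundance` column summing to
#'   `total_cells_per_ml`.
#' @export
absolute_abundance <- function(table, total_cells_per_ml) {
  assert_that(is.data.frame(table) && "rel_abundance" %in% names(table),
              "`table` must carry a `rel_abundance` column.")
  assert_scalar_number(total_cells_per_ml, "total_cells_per_ml", min = 0)
  table$abs_abundance <- table$rel_abundance * total_cells_per_ml
  table
}

#' Select unique identifier windows from full-length marker genes
#'
#' Utility that scans each strain's 16S rRNA (or other marker) gene for a
#' window of the first requested length that occurs in no other strain's
#' gene, preferring the shortest length that works. The resulting windows
#' satisfy the mutual non-substring requirement of
#' [identifier_catalog()].
#'
#' @param genes Named character vector or `DNAStringSet` of full-length
#'   gene sequences, one per strain.
#' @param operon_copies Operon copy numbers, one per strain.
#' @param lengths Candidate window lengths, tried in order. Default
#'   `c(60, 90)`.
#' @return An [identifier_catalog()].
#' @export
select_identifiers <- function(genes, operon_copies, lengths = c(60, 90)) {
  if (inherits(genes, "DNAStringSet")) {
    genes <- setNames(as.character(genes), names(genes))
  }
  genes <- toupper(genes)
  assert_that(!is.null(names(genes)) && !anyDuplicated(names(genes)),
              "`genes` must be uniquely named by strain.")
  assert_that(length(operon_copies) == length(genes),
              "`operon_copies` must have one entry per strain.")
  picked <- character(length(genes))
  for (i in seq_along(genes)) {
    others <- genes[-i]
    found <- NA_character_
    for (L in lengths) {
      n_win <- nchar(genes[i]) - L + 1
      if (n_win < 1) next
      for (off in seq_len(n_win)) {
        cand <- substr(genes[i], off, off + L - 1)
        if (!grepl("^[ACGT]+$", cand)) next
        if (!any(grepl(cand, others, fixed = TRUE))) {
          found <- cand
          break
        }
      }
      if (!is.na(found)) break
    }
    if (is.na(found)) {
      abort(sprintf("No unique identifier window found for strain '%s'.",
                    names(genes)[i]))
    }
    picked[i] <- found
  }
  identifier_catalog(names(genes), picked, operon_copies,
                     lengths = lengths)
}

#' Write a strain count table to TSV
#' @param table A `strain_count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_counts <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
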