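test_that("identifier catalogs reject substring clashes and bad copies", {
  expect_error(
    identifier_catalog(c("A", "B"),
                       c(strrep("ACGT", 15),
                         paste0("AA", strrep("ACGT", 15), "AA")),
                       c(1, 1), lengths = NULL),
    "contained")
  expect_error(
    identifier_catalog("A", "ACGTN", 1, lengths = NULL), "A/C/G/T")
  expect_error(
    identifier_catalog("A", strrep("A", 61), 1), "lengths")
  expect_error(
    identifier_catalog("A", strrep("ACGT", 15), 0), "positive")
  ok <- identifier_catalog("A", strrep("ACGT", 15), 4)
  expect_s3_class(ok, "identifier_catalog")
})

test_that("identifier counting is exact-match, per-read, forward strand", {
  cat3 <- test_catalog()
  withr::with_seed(1, {
    reads_a <- vapply(1:100, function(i)
      embed_read(cat3$identifier_seq[1]), character(1))
  })
  counts <- count_identifiers(reads_a, cat3)
  expect_equal(counts$raw_count, c(100L, 0L, 0L))
  # one mismatched base inside the identifier breaks the match
  mm <- reads_a[1]
  id <- cat3$identifier_seq[1]
  pos <- 20 + 30 # inside the embedded identifier
  orig <- substr(mm, pos, pos)
  substr(mm, pos, pos) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  expect_equal(sum(count_identifiers(mm, cat3)$raw_count), 0L)
  # reverse-complement reads are invisible unless revcomp = TRUE
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads_a[1])))
  expect_equal(sum(count_identifiers(rc, cat3)$raw_count), 0L)
  expect_equal(sum(count_identifiers(rc, cat3, revcomp = TRUE)$raw_count),
               1L)
})

test_that("ambiguous multi-identifier reads are excluded and logged", {
  cat3 <- test_catalog()
  both <- paste0(cat3$identifier_seq[1], "ACGT", cat3$identifier_seq[2])
  single <- paste0("AAAA", cat3$identifier_seq[1], "TTTT")
  expect_message(counts <- count_identifiers(c(both, single), cat3),
                 "multiple identifiers")
  expect_equal(counts$raw_count, c(1L, 0L, 0L))
  expect_equal(attr(counts, "n_ambiguous"), 1L)
})

test_that("counting is invariant to read order and respects proportions", {
  cat2 <- make_identifier_catalog(2, lengths = 60, copies = c(1, 1),
                                  seed = 7)
  gen <- make_reads(cat2, c(S01 = 0.7, S02 = 0.3), n_reads = 10000,
                    read_length = 150, seed = 123)
  counts <- count_identifiers(gen$reads, cat2)
  # bookkeeping: counts equal the generator's truth exactly (error-free)
  expect_equal(counts$raw_count, gen$truth$embedded_count)
  # and the truth itself is a multinomial draw around 7000/3000
  sd_a <- sqrt(10000 * 0.7 * 0.3)
  expect_lt(abs(counts$raw_count[1] - 7000), 3 * sd_a)
  shuffled <- withr::with_seed(5, sample(gen$reads))
  expect_equal(count_identifiers(shuffled, cat2)$raw_count,
               counts$raw_count)
})

test_that("operon correction divides counts by copies and renormalizes", {
  cat2 <- identifier_catalog(c("A", "B"),
                             c(strrep("ACGT", 15), strrep("GGCA", 15)),
                             c(4, 2))
  tbl <- correct_and_normalize(c(A = 100, B = 100), cat2)
  expect_equal(tbl$corrected_count, c(25, 50))
  expect_equal(tbl$rel_abundance, c(1 / 3, 2 / 3))
  expect_equal(sum(tbl$rel_abundance), 1)
  # copies of 1 leave proportions untouched (identity correction)
  cat1 <- identifier_catalog(c("A", "B"),
                             c(strrep("ACGT", 15), strrep("GGCA", 15)),
                             c(1, 1))
  tbl1 <- correct_and_normalize(c(A = 30, B = 70), cat1)
  expect_equal(tbl1$rel_abundance, c(0.3, 0.7))
  # idempotence: correcting corrected counts with copies = 1 changes nothing
  tbl2 <- correct_and_normalize(
    setNames(tbl1$corrected_count, tbl1$strain_id), cat1)
  expect_equal(tbl2$rel_abundance, tbl1$rel_abundance)
  # absent strain
  cat72 <- identifier_catalog(c("A", "B"),
                              c(strrep("ACGT", 15), strrep("GGCA", 15)),
                              c(7, 3))
  tbl3 <- correct_and_normalize(c(A = 0, B = 300), cat72)
  expect_equal(tbl3$rel_abundance, c(0, 1))
  expect_error(correct_and_normalize(c(A = 10, B = 10), cat2,
                                     n_classified = 5), "n_classified")
  expect_warning(empty <- correct_and_normalize(c(A = 0, B = 0), cat2),
                 "empty")
  expect_true(all(is.na(empty$rel_abundance)))
  expect_true(attr(empty, "empty_community"))
})

test_that("absolute abundances anchor to the flow-cytometry total", {
  tbl <- tibble::tibble(strain_id = c("A", "B"),
                        rel_abundance = c(0.25, 0.75))
  out <- absolute_abundance(tbl, 1e9)
  expect_equal(out$abs_abundance, c(2.5e8, 7.5e8))
  expect_equal(sum(out$abs_abundance), 1e9)
  expect_equal(absolute_abundance(tbl, 0)$abs_abundance, c(0, 0))
  expect_error(absolute_abundance(tbl, -1), ">= 0")
  # anchored to the stable post-cycle community density of 1.11e9
  cat2 <- identifier_catalog(c("A", "B"),
                             c(strrep("ACGT", 15), strrep("GGCA", 15)),
                             c(4, 2))
  anchored <- absolute_abundance(
    correct_and_normalize(c(A = 100, B = 100), cat2), 1.11e9)
  expect_equal(anchored$abs_abundance, c(3.7e8, 7.4e8))
})

test_that("known cell abundances round-trip through reads and correction", {
  # cells -> reads: a strain's read share is proportional to cells x copies
  withr::with_seed(99, {
    cat7 <- make_identifier_catalog(7, lengths = c(60, 90), copies = 1:7,
                                    seed = 31)
    cell_rel <- {x <- runif(7, 0.5, 2); x / sum(x)}
    read_prop <- cell_rel * cat7$operon_copies
    read_prop <- read_prop / sum(read_prop)
    n_reads <- 20000
    gen <- make_reads(cat7, setNames(read_prop, cat7$strain_id), n_reads,
                      read_length = 150, seed = 17)
    tbl <- correct_and_normalize(count_identifiers(gen$reads, cat7), cat7)
    # recovered within 3 SD of the multinomial sampling error per strain
    for (i in 1:7) {
      sd_i <- sqrt(n_reads * read_prop[i] * (1 - read_prop[i]))
      tol <- 3 * sd_i / (n_reads * read_prop[i]) * cell_rel[i]
      expect_lt(abs(tbl$rel_abundance[i] - cell_rel[i]), tol + 1e-9)
    }
  })
})

test_that("identifier selection picks windows unique across the catalog", {
  base <- strrep("ACGT", 60)
  genes <- c(g1 = paste0(base, strrep("AC", 40), base),
             g2 = paste0(base, strrep("GT", 40), base),
             g3 = paste0(base, strrep("TTGA", 20), base))
  cat3 <- select_identifiers(genes, operon_copies = c(2, 3, 4),
                             lengths = c(60, 90))
  expect_s3_class(cat3, "identifier_catalog")
  for (i in 1:3) {
    others <- genes[-i]
    expect_false(any(grepl(cat3$identifier_seq[i], others, fixed = TRUE)))
    expect_true(grepl(cat3$identifier_seq[i], genes[i], fixed = TRUE))
  }
  # identical genes admit no unique window
  expect_error(select_identifiers(c(a = base, b = base), c(1, 1)),
               "No unique identifier")
})

test_that("catalogs and reads round-trip through FASTA/FASTQ/TSV files", {
  td <- withr::local_tempdir()
  cat3 <- test_catalog()
  fa <- file.path(td, "catalog.fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(cat3$identifier_seq),
             cat3$strain_id), fa)
  tsv <- file.path(td, "copies.tsv")
  readr::write_tsv(tibble::tibble(strain_id = cat3$strain_id,
                                  operon_copies = cat3$operon_copies), tsv)
  back <- read_identifier_catalog(fa, tsv, lengths = 60)
  expect_equal(back$identifier_seq, cat3$identifier_seq)
  expect_equal(back$operon_copies, cat3$operon_copies)
  fq <- file.path(td, "reads.fastq")
  gen <- make_reads(cat3, setNames(c(0.5, 0.3, 0.2), cat3$strain_id),
                    500, seed = 3, fastq = fq)
  expect_true(file.exists(fq))
  expect_true(file.exists(paste0(fq, ".truth.json")))
  counts <- count_identifiers(fq, cat3)
  expect_equal(counts$raw_count, gen$truth$embedded_count)
})
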