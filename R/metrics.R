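#' Rescale a community matrix to a common sequencing depth
#'
#' Rescales each sample row so its taxa counts sum to `depth` (default
#' 5e4 reads). Values stay continuous — no rounding — so downstream
#' detection thresholds are not subject to floor artifacts.
#'
#' @param m A community matrix tibble: a `sample_id` column, optional
#'   metadata columns (any non-numeric column is treated as metadata),
#'   and one numeric column per taxon. See [community_matrix()].
#' @param depth Target row total. Default `5e4`.
#' @return The matrix with taxa columns rescaled.
#' @export
normalize_depth <- function(m, depth = 5e4) {
  assert_scalar_number(depth, "depth", min = 0, strict_min = TRUE)
  taxa <- taxa_columns(m)
  vals <- as.matrix(m[taxa])
  assert_that(all(vals >= 0), "Community matrix values must be >= 0.")
  totals <- rowSums(vals)
  if (any(totals == 0)) {
    bad <- sample_labels(m)[which(totals == 0)[1]]
    abort(paste0("Sample '", bad, "' has zero total abundance."))
  }
  m[taxa] <- vals / totals * depth
  m
}

# Numeric (taxon) columns of a community matrix; everything non-numeric
# plus known key columns is metadata.
taxa_columns <- function(m) {
  assert_that(is.data.frame(m) && nrow(m) > 0,
              "`m` must be a non-empty community matrix tibble.")
  meta <- c("sample_id", "replicate", "cycle", "regime", "group")
  cand <- setdiff(names(m), meta)
  cand[vapply(m[cand], is.numeric, logical(1))]
}

sample_labels <- function(m) {
  if ("sample_id" %in% names(m)) as.character(m$sample_id)
  else as.character(seq_len(nrow(m)))
}

#' Detected richness of a sample
#'
#' Number of taxa at or above a detection threshold, conventionally
#' presence (`detect_min = 1`) in a row normalized to 5e4 reads
#' ([normalize_depth()]).
#'
#' @param row Numeric vector of (normalized) abundances.
#' @param detect_min Detection threshold. Default 1.
#' @return Integer count of detected taxa.
#' @examples
#' richness(c(5000, 15000, 30000, 0))
#' @export
richness <- function(row, detect_min = 1) {
  assert_that(is.numeric(row), "`row` must be numeric.")
  sum(row >= detect_min)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in natural-log units (nats); zero
#' entries are skipped.
#'
#' @param p Numeric vector of relative abundances summing to 1.
#' @return Shannon index H (nats).
#' @examples
#' shannon(c(0.5, 0.5)) # log(2)
#' @export
shannon <- function(p) {
  assert_that(is.numeric(p) && all(p >= 0), "`p` must be non-negative.")
  assert_that(abs(sum(p) - 1) <= 1e-6, "`p` must sum to 1.")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' \[0, 1\], 0 iff the vectors are identical, 1 for disjoint supports.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Bray-Curtis distance.
#' @examples
#' bray_curtis(c(0.6, 0.4), c(0.2, 0.8)) # 0.4
#' @export
bray_curtis <- function(x, y) {
  assert_that(is.numeric(x) && is.numeric(y) && length(x) == length(y),
              "`x` and `y` must be numeric vectors of equal length.")
  assert_that(all(x >= 0) && all(y >= 0),
              "Abundances must be non-negative.")
  denom <- sum(x + y)
  assert_that(denom > 0, "`x` and `y` must not both be all-zero.")
  sum(abs(x - y)) / denom
}

#' Per-sample Bray-Curtis distance to the group centroid
#'
#' Replicate variability measure: within each group, the centroid is the
#' arithmetic mean abundance vector of the group's samples, and each
#' sample's variability is its Bray-Curtis distance to that centroid.
#' Singleton groups get distance 0 with a warning.
#'
#' @param m A community matrix tibble of relative abundances (see
#'   [community_matrix()]).
#' @param group Character/factor vector of group labels, one per row of
#'   `m`, or the name of a metadata column of `m`. Default: all samples
#'   in one group.
#' @return A tibble: `sample_id`, `group`, `dist_to_centroid`.
#' @examples
#' m <- tibble::tibble(sample_id = c("r1", "r2"),
#'                     a = c(1, 0), b = c(0, 1))
#' centroid_distances(m)
#' @export
centroid_distances <- function(m, group = NULL) {
  taxa <- taxa_columns(m)
  vals <- as.matrix(m[taxa])
  if (is.null(group)) {
    group <- rep("all", nrow(m))
  } else if (length(group) == 1 && group %in% names(m)) {
    group <- as.character(m[[group]])
  }
  assert_that(length(group) == nrow(m),
              "`group` must supply one label per sample.")
  if (any(table(group) < 2)) {
    warn("Singleton group(s) present; their distances are 0.")
  }
  out <- tibble(sample_id = sample_labels(m), group = as.character(group))
  out$dist_to_centroid <- vapply(seq_len(nrow(m)), function(i) {
    rows <- vals[group == group[i], , drop = FALSE]
    if (nrow(rows) < 2) return(0)
    bray_curtis(vals[i, ], colMeans(rows))
  }, numeric(1))
  out
}

#' Pairwise Bray-Curtis distance matrix of a community matrix
#'
#' Computed with [vegan::vegdist()]; exported as a plain square matrix so
#' it can be written to TSV for downstream ordination or permutation
#' testing in external tools.
#'
#' @param m A community matrix tibble.
#' @return A square symmetric matrix with sample ids as dimnames.
#' @export
bc_distance_matrix <- function(m) {
  taxa <- taxa_columns(m)
  d <- as.matrix(vegan::vegdist(as.matrix(m[taxa]), method = "bray"))
  dimnames(d) <- list(sample_labels(m), sample_labels(m))
  d
}

#' Summarise a community matrix: richness and Shannon per sample
#'
#' @param m A community matrix tibble (counts or reads).
#' @param depth Normalization depth passed to [normalize_depth()].
#' @param detect_min Detection threshold passed to [richness()].
#' @return A tibble: `sample_id`, `richness`, `shannon`.
#' @export
community_metrics <- function(m, depth = 5e4, detect_min = 1) {
  norm <- normalize_depth(m, depth)
  taxa <- taxa_columns(norm)
  vals <- as.matrix(norm[taxa])
  tibble(
    sample_id = sample_labels(m),
    richness = apply(vals, 1, richness, detect_min = detect_min),
    shannon = apply(vals, 1, function(r) shannon(r / sum(r)))
  )
}
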