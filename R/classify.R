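#' Classify contact pairs into HiC-Pro-convention categories
#'
#' Canonicalizes mate order (lower chromosome/position first), assigns each
#' end to its restriction fragment, and applies the rule table:
#'
#' * any mate below `min_mapq`: `dumped` (not reported);
#' * different chromosomes: `valid` (trans);
#' * same fragment, inward strands `(+,-)`: `dangling_end`;
#' * same fragment, outward strands `(-,+)`: `self_circle`;
#' * same fragment, equal strands: `dumped` (reported);
#' * adjacent fragments, inward strands: `religation`;
#' * otherwise: `valid` (cis).
#'
#' The `reported` column marks pairs passing the mapping-quality filter (the
#' denominator of the valid-pair ratio); the mapq-dumped bucket is excluded
#' from it.
#'
#' @param pairs Tibble with `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2` and (optionally) `mapq1`, `mapq2`.
#' @param fragment_map A [digest_genome()] fragment map covering all
#'   chromosomes present.
#' @param min_mapq Minimum mapping quality per mate.
#' @return `pairs` in canonical mate order with `fragment1`, `fragment2`,
#'   `category` and `reported` columns added.
#' @examples
#' gn <- toy_genome("alpha", seed = 1)
#' fm <- digest_genome(gn)
#' sim <- simulate_cells(gn, sim_config(n_cells = c(alpha = 3),
#'                                      n_background_barcodes = 0,
#'                                      pairs_per_cell = 100, seed = 2))
#' cls <- classify_pairs(sim$pairs, fm)
#' table(cls$category)
#' @export
classify_pairs <- function(pairs, fragment_map, min_mapq = 10) {
  assert_columns(pairs, c("chrom1", "pos1", "strand1",
                          "chrom2", "pos2", "strand2"), "pair stream")
  if (!"mapq1" %in% names(pairs)) pairs$mapq1 <- 60L
  if (!"mapq2" %in% names(pairs)) pairs$mapq2 <- 60L
  n <- nrow(pairs)

  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos2 < pairs$pos1)
  flip <- function(a, b) list(ifelse(swap, b, a), ifelse(swap, a, b))
  c12 <- flip(pairs$chrom1, pairs$chrom2)
  p12 <- flip(pairs$pos1, pairs$pos2)
  s12 <- flip(pairs$strand1, pairs$strand2)
  q12 <- flip(pairs$mapq1, pairs$mapq2)
  pairs$chrom1 <- c12[[1]]; pairs$chrom2 <- c12[[2]]
  pairs$pos1 <- p12[[1]]; pairs$pos2 <- p12[[2]]
  pairs$strand1 <- s12[[1]]; pairs$strand2 <- s12[[2]]
  pairs$mapq1 <- q12[[1]]; pairs$mapq2 <- q12[[2]]

  f1 <- lookup_fragment(fragment_map, pairs$chrom1, pairs$pos1)
  f2 <- lookup_fragment(fragment_map, pairs$chrom2, pairs$pos2)

  reported <- pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  category <- rep("valid", n)
  same_chr <- pairs$chrom1 == pairs$chrom2
  same_frag <- same_chr & f1 == f2
  inward <- pairs$strand1 == "+" & pairs$strand2 == "-"
  outward <- pairs$strand1 == "-" & pairs$strand2 == "+"
  category[same_frag & inward] <- "dangling_end"
  category[same_frag & outward] <- "self_circle"
  category[same_frag & pairs$strand1 == pairs$strand2] <- "dumped"
  category[same_chr & abs(f1 - f2) == 1 & inward] <- "religation"
  category[!reported] <- "dumped"

  pairs$fragment1 <- f1
  pairs$fragment2 <- f2
  pairs$category <- category
  pairs$reported <- reported
  as_tibble(pairs)
}

#' Flag PCR duplicates within each cell
#'
#' A pair is a duplicate iff an earlier pair of the same cell has the
#' identical coordinate tuple (`chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#' `strand2`); the first occurrence is kept and row order is preserved.
#'
#' @param pairs Classified (canonical-order) pairs with a `cell_id` column.
#' @return `pairs` with a logical `duplicate` column.
#' @export
deduplicate <- function(pairs) {
  assert_columns(pairs, c("cell_id", "chrom1", "pos1", "strand1",
                          "chrom2", "pos2", "strand2"), "pair stream")
  key <- paste(pairs$cell_id, pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  pairs$duplicate <- duplicated(key)
  pairs
}

mito_chroms_of <- function(genome) {
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  assert_columns(sizes, c("chrom", "class"), "chromosome table")
  sizes$chrom[sizes$class == "mito"]
}

#' Per-cell quality-control metrics
#'
#' Computes the HiC-Pro-style per-barcode QC panel. The valid-pair ratio uses
#' valid pairs *prior to* deduplication over reported pairs (the efficiency
#' benchmark); the duplication rate is the duplicated share of valid pairs;
#' cis/trans counts and the mito-nuclear false-positive rate use unique
#' (deduplicated) valid pairs.
#'
#' @param pairs Output of [classify_pairs()] + [deduplicate()].
#' @param genome A `toy_genome`, list of them, or a chromosome table with
#'   `chrom` and `class` columns (used to locate mitochondrial chromosomes;
#'   pass `NULL` to skip the false-positive rate).
#' @return Tibble with one row per `cell_id`: `total_pairs`,
#'   `reported_pairs`, `valid_pairs`, `unique_valid_pairs`, `dup_rate`,
#'   `cis`, `trans`, `log2_cis_trans`, `log2_trans_cis`, `fp_rate`,
#'   `valid_pair_ratio`, `reported_pair_ratio`.
#' @export
cell_qc <- function(pairs, genome = NULL) {
  assert_columns(pairs, c("cell_id", "category", "reported", "duplicate"),
                 "classified pair stream")
  mito <- if (is.null(genome)) character(0) else mito_chroms_of(genome)

  is_valid <- pairs$category == "valid"
  uniq_valid <- is_valid & !pairs$duplicate
  one_mito <- (pairs$chrom1 %in% mito) != (pairs$chrom2 %in% mito)

  qc <- pairs |>
    mutate(.valid = is_valid, .uval = uniq_valid, .mito1 = one_mito) |>
    group_by(.data$cell_id) |>
    summarise(
      total_pairs = dplyr::n(),
      reported_pairs = sum(.data$reported),
      valid_pairs = sum(.data$.valid),
      unique_valid_pairs = sum(.data$.uval),
      cis = sum(.data$.uval & .data$chrom1 == .data$chrom2),
      trans = sum(.data$.uval & .data$chrom1 != .data$chrom2),
      fp_hits = sum(.data$.uval & .data$.mito1)
    ) |>
    mutate(
      dup_rate = ifelse(.data$valid_pairs > 0,
                        1 - .data$unique_valid_pairs / .data$valid_pairs, NA_real_),
      log2_cis_trans = log2((.data$cis + 1) / (.data$trans + 1)),
      log2_trans_cis = -.data$log2_cis_trans,
      fp_rate = if (length(mito) > 0) {
        ifelse(.data$unique_valid_pairs > 0,
               .data$fp_hits / .data$unique_valid_pairs, NA_real_)
      } else NA_real_,
      valid_pair_ratio = ifelse(.data$reported_pairs > 0,
                                .data$valid_pairs / .data$reported_pairs, NA_real_),
      reported_pair_ratio = .data$reported_pairs / .data$total_pairs
    ) |>
    select(-"fp_hits")
  if (any(qc$reported_pairs == 0)) {
    warn("some cells have zero reported pairs; their valid-pair ratio is NA")
  }
  qc
}

#' Mito-nuclear false-positive rate per cell
#'
#' Fraction of unique valid pairs with exactly one end on a mitochondrial
#' chromosome (pairs with both ends on the mito genome are cis-mito contacts
#' and are not counted).
#'
#' @inheritParams cell_qc
#' @return Tibble `cell_id`, `unique_valid_pairs`, `fp_rate`.
#' @export
false_positive_rate <- function(pairs, genome) {
  mito <- mito_chroms_of(genome)
  if (length(mito) == 0) {
    abort("the genome declares no mitochondrial chromosome")
  }
  cell_qc(pairs, genome) |>
    select("cell_id", "unique_valid_pairs", "fp_rate")
}
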