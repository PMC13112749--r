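#' Rank barcodes by unique valid pair counts
#'
#' Stable descending sort of per-barcode unique valid pair counts; ties are
#' broken by lexicographic barcode order so the curve is identical across
#' runs.
#'
#' @param counts Tibble with `cell_id` and a count column (default
#'   `unique_valid_pairs`), or a named numeric vector.
#' @param count_col Name of the count column.
#' @return Tibble `cell_id`, `count`, `rank` (1 = largest).
#' @export
rank_barcodes <- function(counts, count_col = "unique_valid_pairs") {
  if (!is.data.frame(counts)) {
    counts <- tibble(cell_id = names(counts), !!count_col := unname(counts))
  }
  assert_columns(counts, c("cell_id", count_col), "barcode counts")
  if (nrow(counts) < 3) abort("need at least 3 barcodes to rank")
  out <- counts |>
    select("cell_id", count = dplyr::all_of(count_col)) |>
    arrange(dplyr::desc(.data$count), .data$cell_id) |>
    mutate(rank = dplyr::row_number())
  out
}

# Normalized log-log difference curve of a descending barcode-rank curve.
# After min-max normalization a concave decreasing curve lies above the
# anti-diagonal; the difference d = x + y - 1 measures that excess.
kneedle_difference <- function(rank, count) {
  x <- log10(rank)
  y <- log10(pmax(count, 0.5))
  x <- (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)
  y <- (y - min(y)) / max(max(y) - min(y), .Machine$double.eps)
  x + y - 1
}

# Sharpest knee of a descending rank curve: the point preceding the largest
# drop of the Kneedle difference curve within a short lookahead window (1%
# of the curve), so cliffs blurred over a few interleaved barcodes still
# register. Two acceptance gates: the drop must exceed a sensitivity-scaled
# geometric threshold (the x-term of the difference curve cancels the
# steep-but-smooth head of a power-law profile), and the count drop must be
# significant against Poisson shot noise (log-count steps between counts of
# order 1, as at the tail of the background, are never knees). Returns NULL
# when no drop passes both gates.
sharpest_knee <- function(rank, count, sensitivity, min_drop = 0.02,
                          min_noise_score = 5) {
  n <- length(count)
  if (n < 3) return(NULL)
  d <- kneedle_difference(rank, count)
  cnt <- pmax(count, 0.5)
  w <- max(1L, as.integer(ceiling(0.01 * n)))
  drops <- numeric(n - 1)
  jstar <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    win <- (i + 1):min(i + w, n)
    j <- win[which.min(d[win])]
    drops[i] <- d[i] - d[j]
    jstar[i] <- j
  }
  dlog <- log10(cnt[-n] / cnt[jstar])
  noise_score <- dlog * (cnt[-n] * cnt[jstar])^0.25
  ok <- drops >= sensitivity * min_drop &
    noise_score >= sensitivity * min_noise_score
  if (!any(ok)) return(NULL)
  # among gated candidates, pin the knee to the steepest single step — the
  # actual collapse point rather than the difference-curve peak before it
  cand <- which(ok)
  step <- d[-n] - d[-1]
  cand[which.max(step[cand])]
}

#' Two-knee cell calling on the barcode rank curve
#'
#' Works on the Kneedle difference curve of the min-max-normalized
#' (log10 rank, log10 count) profile. A knee is the point immediately
#' preceding the largest single-step drop of the difference curve, accepted
#' when that drop exceeds a sensitivity-scaled threshold; this pins the knee
#' to the count cliff even when the called-cell plateau itself is curved
#' (where the classical difference-curve arg-max drifts into the plateau).
#' `knee2`, found on the full curve, separates valid cells from background;
#' `knee1`, found on the sub-curve of ranks up to `knee2`, separates
#' doublet-prone high-count barcodes from valid cells. Barcodes are labelled
#' `doublet_prone` (rank <= knee1), `valid` (knee1 < rank <= knee2) and
#' `background` (rank > knee2). A featureless curve yields an explicit
#' no-knee result with every barcode labelled background.
#'
#' @param curve Output of [rank_barcodes()].
#' @param sensitivity Positive multiplier on the acceptance threshold
#'   (Kneedle's S; larger is more conservative).
#' @return A `knee_call`: list with `knee1`, `knee2` (ranks; 0 / NA when not
#'   found), `found` flag and `barcodes` (the curve plus a `label` column).
#' @export
find_knees <- function(curve, sensitivity = 1) {
  assert_columns(curve, c("cell_id", "count", "rank"), "rank curve")
  if (nrow(curve) < 10) abort("need at least 10 barcodes to locate knees")
  curve <- arrange(curve, .data$rank)

  k2 <- sharpest_knee(curve$rank, curve$count, sensitivity)

  if (is.null(k2)) {
    warn("no knee found: the rank curve is featureless; labelling all barcodes background")
    call <- list(knee1 = NA_integer_, knee2 = NA_integer_, found = FALSE,
                 barcodes = mutate(curve, label = "background"))
    class(call) <- "knee_call"
    return(call)
  }

  knee1 <- 0L
  if (k2 >= 10) {
    sub <- curve[seq_len(k2), , drop = FALSE]
    k1 <- sharpest_knee(sub$rank, sub$count, sensitivity)
    # doublet-prone barcodes are a high-count minority: a candidate in the
    # lower half of the called cells is an edge artifact of the sub-curve,
    # not a doublet boundary
    if (!is.null(k1) && k1 <= k2 / 2) knee1 <- k1
  }

  label <- dplyr::case_when(
    curve$rank <= knee1 ~ "doublet_prone",
    curve$rank <= k2 ~ "valid",
    TRUE ~ "background"
  )
  call <- list(knee1 = as.integer(knee1), knee2 = as.integer(k2), found = TRUE,
               barcodes = mutate(curve, label = label))
  class(call) <- "knee_call"
  call
}

#' @export
print.knee_call <- function(x, ...) {
  if (!x$found) {
    cat("<knee_call> no knee found; all barcodes background\n")
  } else {
    cat(sprintf("<knee_call> knee1 = %d, knee2 = %d; %d valid / %d barcodes\n",
                x$knee1, x$knee2, sum(x$barcodes$label == "valid"),
                nrow(x$barcodes)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.knee_call <- function(x, ...) x$barcodes

#' @exportS3Method generics::glance
glance.knee_call <- function(x, ...) {
  tibble(knee1 = x$knee1, knee2 = x$knee2, found = x$found,
         n_doublet_prone = sum(x$barcodes$label == "doublet_prone"),
         n_valid = sum(x$barcodes$label == "valid"),
         n_background = sum(x$barcodes$label == "background"))
}

#' Assign valid cells to species in a barnyard experiment
#'
#' A cell is assigned to a species when at least `threshold` (default 0.89,
#' inclusive) of its unique valid pairs map to that species' genome;
#' otherwise it is a cross-species doublet. Exactly two species are required
#' and the rule is symmetric under relabelling.
#'
#' @param species_counts Tibble with `cell_id` and one count column per
#'   species (unique valid pairs mapped to each genome).
#' @param threshold Minimum within-species fraction, inclusive.
#' @return Tibble `cell_id`, per-species fractions, `label` (a species tag or
#'   `"doublet"`). Cells with zero unique valid pairs are dropped with a
#'   warning.
#' @export
assign_species <- function(species_counts, threshold = 0.89) {
  assert_columns(species_counts, "cell_id", "species counts")
  sp <- setdiff(names(species_counts), "cell_id")
  if (length(sp) != 2) abort("exactly two species count columns are required")
  tot <- species_counts[[sp[1]]] + species_counts[[sp[2]]]
  if (any(tot == 0)) {
    warn(sprintf("%d cell(s) with zero unique valid pairs excluded", sum(tot == 0)))
    species_counts <- species_counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  f1 <- species_counts[[sp[1]]] / tot
  f2 <- 1 - f1
  label <- ifelse(f1 >= threshold, sp[1], ifelse(f2 >= threshold, sp[2], "doublet"))
  tibble(cell_id = species_counts$cell_id,
         !!paste0("frac_", sp[1]) := f1,
         !!paste0("frac_", sp[2]) := f2,
         label = label)
}

#' Cross-species collision rate
#'
#' @param species_calls Output of [assign_species()] restricted to valid
#'   (post-knee) cells.
#' @return Tibble `n_valid_cells`, `n_doublets`, `rate` where
#'   `rate = n_doublets / n_valid_cells` (the denominator includes the
#'   doublets themselves).
#' @export
collision_rate <- function(species_calls) {
  assert_columns(species_calls, c("cell_id", "label"), "species calls")
  n <- nrow(species_calls)
  if (n == 0) abort("no valid cells; collision rate undefined")
  nd <- sum(species_calls$label == "doublet")
  tibble(n_valid_cells = n, n_doublets = nd, rate = nd / n)
}

#' Per-cell unique valid pair counts split by species
#'
#' Convenience bridge from a classified, deduplicated pair stream to the
#' input of [assign_species()]: counts each cell's unique valid pairs whose
#' ends both lie on chromosomes of one species.
#'
#' @param pairs Classified + deduplicated pairs.
#' @param genomes List of `toy_genome` objects (two species).
#' @return Tibble `cell_id`, one column per species.
#' @export
species_pair_counts <- function(pairs, genomes) {
  sizes <- chrom_sizes(genomes)
  sp_of <- setNames(sizes$species, sizes$chrom)
  keep <- pairs$category == "valid" & !pairs$duplicate
  ss <- pairs[keep, c("cell_id", "chrom1", "chrom2")]
  ss$sp1 <- sp_of[ss$chrom1]
  ss$sp2 <- sp_of[ss$chrom2]
  ss <- ss[!is.na(ss$sp1) & ss$sp1 == ss$sp2, ]  # cross-species chimeras dropped
  out <- ss |>
    count(.data$cell_id, .data$sp1) |>
    tidyr::pivot_wider(names_from = "sp1", values_from = "n", values_fill = 0L)
  for (sp in unique(sizes$species)) {
    if (!sp %in% names(out)) out[[sp]] <- 0L
  }
  out
}
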