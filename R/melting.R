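#' Select long B-compartment genes as regions of interest
#'
#' Keeps genes spanning at least `min_length` whose bin-length-weighted
#' majority of overlapping compartment-eigenvector bins is negative (B
#' compartment). Region coordinates are aligned outward to the track's bin
#' grid. Genes on chromosomes the eigen track does not cover are skipped
#' with a warning.
#'
#' @param genes Tibble `chrom`, `start`, `end`, `gene_id`.
#' @param eigen_track Output of [compartment_eigenvector()].
#' @param min_length Minimum gene span in bp (default 300 kb).
#' @param bin_size Grid for outward rounding (default 50 kb).
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (grid-aligned),
#'   `length`, `b_weight` (fraction of overlapped bin length with negative
#'   eigenvector).
#' @export
select_long_b_genes <- function(genes, eigen_track, min_length = 300e3,
                                bin_size = 50e3) {
  assert_columns(genes, c("chrom", "start", "end", "gene_id"), "gene table")
  assert_columns(eigen_track, c("chrom", "start", "end", "eigen"), "eigen track")
  long <- filter(genes, .data$end - .data$start >= min_length)
  covered <- unique(eigen_track$chrom)
  off <- filter(long, !.data$chrom %in% covered)
  if (nrow(off) > 0) {
    warn(sprintf("%d gene(s) on chromosomes without eigen coverage skipped", nrow(off)))
    long <- filter(long, .data$chrom %in% covered)
  }
  purrr::map_dfr(seq_len(nrow(long)), function(i) {
    g <- long[i, ]
    tt <- filter(eigen_track, .data$chrom == g$chrom,
                 .data$end > g$start, .data$start < g$end, !is.na(.data$eigen))
    if (nrow(tt) == 0) return(tibble())
    w <- pmin(tt$end, g$end) - pmax(tt$start, g$start)
    b_weight <- sum(w[tt$eigen < 0]) / sum(w)
    if (b_weight <= 0.5) return(tibble())
    tibble(gene_id = g$gene_id, chrom = g$chrom,
           start = floor(g$start / bin_size) * bin_size,
           end = ceiling(g$end / bin_size) * bin_size,
           length = g$end - g$start, b_weight = b_weight)
  })
}

#' Cluster cells into melting and concretion states
#'
#' Ward hierarchical clustering of per-cell insulation scores restricted to
#' a region of interest: per-bin mean imputation of missing scores, per-bin
#' z-scaling, Euclidean distance, Ward linkage, tree cut at k = 2. The
#' cluster with the lower median (raw) insulation score is the melting
#' state. Cells downsampled to equal unique valid pairs upstream are
#' assumed; a cut producing an empty or singleton cluster marks the
#' clustering unstable with a warning.
#'
#' @param scores Long tibble of per-cell insulation scores in the ROI:
#'   `cell_id`, `bin_id` (or `start`), `score`.
#' @param linkage `"ward.D2"` (squared-Euclidean Ward, default) or
#'   `"ward.D"`.
#' @return A `state_clustering`: list with `cells` (tibble `cell_id`,
#'   `cluster`, `state`), `medians`, `linkage`, `stable`.
#' @export
cluster_states <- function(scores, linkage = c("ward.D2", "ward.D")) {
  linkage <- match.arg(linkage)
  bin_col <- if ("bin_id" %in% names(scores)) "bin_id" else "start"
  assert_columns(scores, c("cell_id", bin_col, "score"), "insulation scores")
  wide <- scores |>
    select("cell_id", bin = dplyr::all_of(bin_col), "score") |>
    tidyr::pivot_wider(names_from = "bin", values_from = "score")
  X <- as.matrix(wide[, -1, drop = FALSE])
  rownames(X) <- wide$cell_id
  if (nrow(X) < 4) abort("need at least 4 cells to cluster states")
  if (ncol(X) < 3) abort("need at least 3 ROI bins to cluster states")

  for (j in seq_len(ncol(X))) {   # mean imputation per bin
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  Z <- scale(X)
  Z[, !is.finite(apply(Z, 2, stats::sd))] <- 0
  Z[!is.finite(Z)] <- 0

  hc <- hclust(dist(Z), method = linkage)
  cl <- cutree(hc, k = 2)
  med <- vapply(1:2, function(k) median(X[cl == k, ], na.rm = TRUE), numeric(1))
  melting_cluster <- which.min(med)
  state <- ifelse(cl == melting_cluster, "melting", "concretion")
  stable <- min(table(cl)) > 1 && length(unique(cl)) == 2
  if (!stable) warn("degenerate cut: empty or singleton cluster; clustering unstable")

  structure(list(
    cells = tibble(cell_id = rownames(X), cluster = unname(cl),
                   state = unname(state)),
    medians = tibble(state = ifelse(seq_along(med) == melting_cluster,
                                    "melting", "concretion"),
                     median_score = med),
    linkage = linkage, stable = stable, hclust = hc
  ), class = "state_clustering")
}

#' @export
print.state_clustering <- function(x, ...) {
  cat(sprintf("<state_clustering> %d melting / %d concretion cells (%s)%s\n",
              sum(x$cells$state == "melting"),
              sum(x$cells$state == "concretion"),
              x$linkage, if (x$stable) "" else " [unstable]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.state_clustering <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.state_clustering <- function(x, ...) {
  tibble(n_melting = sum(x$cells$state == "melting"),
         n_concretion = sum(x$cells$state == "concretion"),
         linkage = x$linkage, stable = x$stable)
}

#' One-sided Kolmogorov-Smirnov melting score of a region
#'
#' Pools all (cell, bin) insulation scores of the region per state and
#' computes the one-sided KS statistic
#' `D = sup_x (F_melting(x) - F_concretion(x))` — positive when the melting
#' cluster is shifted toward lower insulation — with the asymptotic
#' one-sided p-value `p = exp(-2 D^2 m n / (m + n))`. A region is called
#' significantly molten when `p < 1e-5`.
#'
#' @param scores Long tibble `cell_id`, `score` (ROI-restricted insulation
#'   scores; additional columns ignored).
#' @param clustering A [cluster_states()] result (or a tibble `cell_id`,
#'   `state`).
#' @param alpha Significance level on the p-value.
#' @return Tibble `D`, `p_value`, `significant`, `n_melting`,
#'   `n_concretion`.
#' @export
melting_score <- function(scores, clustering, alpha = 1e-5) {
  assert_columns(scores, c("cell_id", "score"), "insulation scores")
  cells <- if (inherits(clustering, "state_clustering")) clustering$cells else clustering
  assert_columns(cells, c("cell_id", "state"), "state labels")
  df <- scores |>
    left_join(select(cells, "cell_id", "state"), by = "cell_id") |>
    filter(!is.na(.data$state), !is.na(.data$score))
  xm <- df$score[df$state == "melting"]
  xc <- df$score[df$state == "concretion"]
  m <- length(xm); n <- length(xc)
  if (m == 0 || n == 0) abort("both clusters must contribute scores")
  D <- ks_one_sided(xm, xc)
  p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
  tibble(D = D, p_value = p, significant = p < alpha,
         n_melting = m, n_concretion = n)
}

# sup_x (F_a(x) - F_b(x)) over the pooled sample points (never negative:
# the sup of a difference of ECDFs at -Inf is 0).
ks_one_sided <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- ecdf(a)(grid)
  Fb <- ecdf(b)(grid)
  max(0, max(Fa - Fb))
}

#' Depth reliability guard for state detection
#'
#' State separation degrades at shallow depth; this lists cells whose unique
#' valid pairs fall below the reliability threshold so downstream clustering
#' results can carry a flag (clustering still proceeds).
#'
#' @param counts Tibble `cell_id`, `unique_valid_pairs` (e.g. from
#'   [cell_qc()]).
#' @param threshold Minimum reliable depth (pairs per cell).
#' @return List with `low_cells` (tibble), `n_low`, `flag` (TRUE when any
#'   cell is shallow), `global` (TRUE when all cells are shallow).
#' @export
depth_guard <- function(counts, threshold = 250e3) {
  assert_columns(counts, c("cell_id", "unique_valid_pairs"), "depth table")
  low <- filter(counts, .data$unique_valid_pairs < threshold)
  if (nrow(low) == nrow(counts) && nrow(low) > 0) {
    warn(sprintf("all cells below %s unique valid pairs; state calls unreliable",
                 format(threshold, big.mark = ",")))
  } else if (nrow(low) > 0) {
    warn(sprintf("%d cell(s) below the %s-pair reliability threshold",
                 nrow(low), format(threshold, big.mark = ",")))
  }
  list(low_cells = low, n_low = nrow(low), flag = nrow(low) > 0,
       global = nrow(low) == nrow(counts) && nrow(low) > 0)
}
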