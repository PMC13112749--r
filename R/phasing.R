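#' Early/late replication score per cell (repli-score)
#'
#' Each unique valid pair contributes two endpoints. Endpoints falling in an
#' early or late replication domain are counted and the score is the
#' pseudocounted ratio `(n_early + 1) / (n_late + 1)`; a higher ratio places
#' the cell nearer early S-phase. Cells are ranked by descending ratio
#' (rank 1 = most early). Cells with no endpoint in either class are flagged
#' uninformative.
#'
#' @param pairs Unique valid pairs with `cell_id`.
#' @param repli_domains Tibble `chrom`, `start`, `end`, `class`
#'   (`early`/`late`), half-open bp intervals.
#' @return Tibble `cell_id`, `n_early`, `n_late`, `ratio`, `rank`,
#'   `informative`.
#' @export
repli_score <- function(pairs, repli_domains) {
  assert_columns(pairs, c("cell_id", "chrom1", "pos1", "chrom2", "pos2"),
                 "pair stream")
  assert_columns(repli_domains, c("chrom", "start", "end", "class"),
                 "replication domains")
  ends <- tibble(cell_id = rep(pairs$cell_id, 2),
                 chrom = c(pairs$chrom1, pairs$chrom2),
                 pos = c(pairs$pos1, pairs$pos2))
  ends$class <- interval_class(ends$chrom, ends$pos, repli_domains)
  out <- ends |>
    group_by(.data$cell_id) |>
    summarise(n_early = sum(.data$class == "early", na.rm = TRUE),
              n_late = sum(.data$class == "late", na.rm = TRUE)) |>
    mutate(ratio = (.data$n_early + 1) / (.data$n_late + 1),
           informative = .data$n_early + .data$n_late > 0)
  out <- arrange(out, dplyr::desc(.data$ratio), .data$cell_id)
  out$rank <- seq_len(nrow(out))
  if (any(!out$informative)) {
    warn(sprintf("%d cell(s) with no endpoints in replication domains",
                 sum(!out$informative)))
  }
  out
}

# Class of the covering half-open interval (NA when uncovered).
interval_class <- function(chrom, pos, domains) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    dd <- domains[domains$chrom == ch, ]
    if (nrow(dd) == 0) next
    dd <- dd[order(dd$start), ]
    ii <- which(chrom == ch)
    k <- findInterval(pos[ii] - 1, dd$start)
    hit <- k >= 1 & pos[ii] - 1 < dd$end[pmax(k, 1)]
    out[ii[hit]] <- dd$class[k[hit]]
  }
  out
}

#' Sex-chromosome haploid score per cell
#'
#' Quantifies sex-chromosome content: `f_sex`, the fraction of contact
#' endpoints on X or Y, divided by the diploid (XY reference) expectation
#' `e_dip = (L_X + L_Y) / (2 L_autosome + L_X + L_Y)`. Diploid cells score
#' about 1; haploid cells (one autosome complement, one sex chromosome)
#' score higher, and a cell is called haploid at `score >= threshold`
#' (default 1.5). The score is invariant to the cell's total contact count.
#'
#' @param pairs Unique valid pairs with `cell_id`.
#' @param genome Genome (or chromosome table) declaring `sex_X` and `sex_Y`
#'   chromosome classes.
#' @param threshold Haploid call threshold.
#' @return Tibble `cell_id`, `n_endpoints`, `f_sex`, `e_dip`, `score`,
#'   `ploidy_call`.
#' @export
haploid_score <- function(pairs, genome, threshold = 1.5) {
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  assert_columns(sizes, c("chrom", "length", "class"), "chromosome table")
  lx <- sum(sizes$length[sizes$class == "sex_X"])
  ly <- sum(sizes$length[sizes$class == "sex_Y"])
  la <- sum(sizes$length[sizes$class == "autosome"])
  if (lx == 0 || ly == 0) {
    abort("genome must declare sex_X and sex_Y chromosomes")
  }
  e_dip <- (lx + ly) / (2 * la + lx + ly)
  sex_chroms <- sizes$chrom[sizes$class %in% c("sex_X", "sex_Y")]
  nuc_chroms <- sizes$chrom[sizes$class != "mito"]

  ends <- tibble(cell_id = rep(pairs$cell_id, 2),
                 chrom = c(pairs$chrom1, pairs$chrom2)) |>
    filter(.data$chrom %in% nuc_chroms)
  out <- ends |>
    group_by(.data$cell_id) |>
    summarise(n_endpoints = dplyr::n(),
              f_sex = mean(.data$chrom %in% sex_chroms)) |>
    mutate(e_dip = e_dip,
           score = .data$f_sex / e_dip,
           ploidy_call = ifelse(.data$score >= threshold, "haploid", "diploid"))
  out
}

#' Compare trans/cis ratios between cell groups
#'
#' Summarises per-group distributions of the log2 trans/cis ratio and tests
#' the two groups with a two-sided Wilcoxon rank-sum test. Groups smaller
#' than 3 yield summary statistics without a test.
#'
#' @param qc [cell_qc()] output (needs `cell_id`, `log2_trans_cis`).
#' @param groups Tibble `cell_id`, `group` (e.g. ploidy calls).
#' @return List with `stats` (per-group n, median, IQR), `p_value`,
#'   `statistic` (NA when untested).
#' @export
group_compare_trans_cis <- function(qc, groups) {
  assert_columns(qc, c("cell_id", "log2_trans_cis"), "QC table")
  assert_columns(groups, c("cell_id", "group"), "group table")
  df <- dplyr::inner_join(select(qc, "cell_id", "log2_trans_cis"), groups,
                          by = "cell_id")
  gl <- unique(df$group)
  if (length(gl) != 2) abort("exactly two groups are required")
  stats_tb <- df |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              median_log2_trans_cis = median(.data$log2_trans_cis),
              iqr = stats::IQR(.data$log2_trans_cis))
  if (any(stats_tb$n < 3)) {
    warn("a group has fewer than 3 cells; rank-sum test skipped")
    return(list(stats = stats_tb, p_value = NA_real_, statistic = NA_real_))
  }
  # exact distribution for small tie-free groups, normal approximation
  # otherwise (wilcox.test's own switching rule); the first group in
  # alphabetical order is the reference of the reported U statistic
  wt <- suppressWarnings(wilcox.test(log2_trans_cis ~ group, data = df))
  list(stats = stats_tb, p_value = wt$p.value, statistic = unname(wt$statistic))
}
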