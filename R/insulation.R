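#' Multi-window insulation (TAD-separation) scores
#'
#' For every window size `w` between `min_depth` and `max_depth` (in bp,
#' stepped by `step`), the diamond statistic of bin `i` is the mean balanced
#' count over the `w x w` block of contacts spanning the bin — rows
#' `[i-w, i-1]` against columns `[i+1, i+w]`, excluding the anchor bin
#' itself. Only full windows count: bins where the largest window does not
#' fit are masked rather than truncated. Each window's profile is z-scored
#' per chromosome and the final insulation score is the mean of the
#' z-scores across window sizes; lower scores mark stronger boundaries.
#'
#' @param mat A `contact_matrix` at the track resolution (balanced counts are
#'   used when [ice_balance()] has been run).
#' @param min_depth,max_depth,step Window range in bp; must be multiples of
#'   the matrix bin size.
#' @return Tibble `chrom`, `start`, `end`, `bin_id`, `score`, `valid`. A
#'   chromosome shorter than twice the largest window yields an all-masked
#'   track with a warning.
#' @export
insulation_scores <- function(mat, min_depth = 200e3, max_depth = 750e3,
                              step = 50e3) {
  stopifnot(inherits(mat, "contact_matrix"))
  res <- mat$bin_size
  depths <- seq(min_depth, max_depth, by = step)
  if (any(depths %% res != 0)) {
    abort("window depths must be multiples of the matrix bin size")
  }
  windows <- unique(depths %/% res)
  wmax <- max(windows)

  purrr::map_dfr(unique(mat$bins$chrom), function(ch) {
    dd <- chrom_dense(mat, ch)
    n <- nrow(dd$mat)
    out <- mutate(dd$bins, score = NA_real_, valid = FALSE)
    if (n < 2 * wmax + 1) {
      warn(sprintf("chromosome '%s' shorter than twice the largest window; track masked", ch))
      return(out)
    }
    z <- matrix(NA_real_, n, length(windows))
    for (wi in seq_along(windows)) {
      w <- windows[wi]
      dm <- diamond_means(dd$mat, w)
      mu <- mean(dm, na.rm = TRUE)
      sg <- stats::sd(dm, na.rm = TRUE)
      z[, wi] <- if (is.na(sg) || sg == 0) ifelse(is.na(dm), NA, 0) else (dm - mu) / sg
    }
    core <- seq_len(n) > wmax & seq_len(n) <= n - wmax
    score <- rowMeans(z)
    score[!core] <- NA_real_
    out$score <- score
    out$valid <- core & !is.na(score)
    out
  })
}

# Mean of the w x w diamond at each bin via 2-D prefix sums; NA outside
# full-window positions.
diamond_means <- function(M, w) {
  n <- nrow(M)
  if (n < 2 * w + 1) return(rep(NA_real_, n))
  P <- matrix(0, n + 1, n + 1)
  P[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  i <- (w + 1):(n - w)
  r1 <- i - w; r2 <- i - 1; c1 <- i + 1; c2 <- i + w
  s <- P[cbind(r2 + 1, c2 + 1)] - P[cbind(r1, c2 + 1)] -
    P[cbind(r2 + 1, c1)] + P[cbind(r1, c1)]
  out <- rep(NA_real_, n)
  out[i] <- s / (w * w)
  out
}

#' Per-cell insulation tracks on one chromosome
#'
#' Bins each cell's cis pairs on `chrom` separately and computes its
#' insulation track. Per-cell matrices are far too sparse for stable
#' iterative correction, so raw counts are used; the per-chromosome
#' z-scoring inside [insulation_scores()] absorbs per-cell depth scale
#' (cells should additionally be downsampled to equal unique valid pairs
#' upstream when states are compared).
#'
#' @param pairs Unique valid pairs with `cell_id`.
#' @param genome Genome or chromosome table.
#' @param chrom Chromosome to process.
#' @param bin_size Bin size in bp.
#' @inheritParams insulation_scores
#' @return Long tibble: `cell_id` plus the [insulation_scores()] columns.
#' @export
insulation_by_cell <- function(pairs, genome, chrom, bin_size = 50e3,
                               min_depth = 200e3, max_depth = 750e3,
                               step = 50e3) {
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  sizes <- filter(sizes, .data$chrom == !!chrom)
  if (nrow(sizes) == 0) abort(sprintf("chromosome '%s' not in genome", chrom))
  cis <- filter(pairs, .data$chrom1 == !!chrom, .data$chrom2 == !!chrom)
  purrr::map_dfr(split(cis, cis$cell_id), function(cp) {
    mat <- bin_contacts(cp, sizes, bin_size = bin_size)
    tr <- insulation_scores(mat, min_depth = min_depth,
                            max_depth = max_depth, step = step)
    mutate(tr, cell_id = cp$cell_id[1], .before = 1)
  })
}

#' Call insulation boundaries
#'
#' Boundaries are local minima of the insulation score whose prominence —
#' the score rise required on *both* sides before a lower value occurs —
#' reaches `delta`. Minima within `merge_within` bins of each other are
#' merged to the deeper one. Lowering `delta` never removes a boundary.
#'
#' @param track Output of [insulation_scores()].
#' @param delta Minimum prominence.
#' @param merge_within Merge radius in bins.
#' @return Tibble of boundary bins: `chrom`, `start`, `end`, `bin_id`,
#'   `score`, `prominence`.
#' @export
call_boundaries <- function(track, delta = 0.01, merge_within = 2) {
  assert_columns(track, c("chrom", "start", "bin_id", "score"), "insulation track")
  if (delta <= 0) abort("`delta` must be positive")
  empty <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  bin_id = integer(0), score = numeric(0),
                  prominence = numeric(0))
  out <- purrr::map_dfr(unique(track$chrom), function(ch) {
    tt <- arrange(filter(track, .data$chrom == ch, !is.na(.data$score)), .data$start)
    s <- tt$score
    n <- length(s)
    if (n < 3) return(tibble())
    cand <- which(vapply(2:(n - 1), function(i) {
      s[i] <= s[i - 1] && s[i] <= s[i + 1] && (s[i] < s[i - 1] || s[i] < s[i + 1])
    }, logical(1))) + 1L
    prom <- vapply(cand, function(i) side_prominence(s, i), numeric(1))
    keep <- cand[prom >= delta]
    prom <- prom[prom >= delta]
    if (length(keep) == 0) return(tibble())
    # merge near-adjacent minima, deeper one wins
    ord <- order(tt$bin_id[keep])
    keep <- keep[ord]; prom <- prom[ord]
    merged <- list()
    cur <- 1
    for (j in seq_along(keep)[-1]) {
      if (tt$bin_id[keep[j]] - tt$bin_id[keep[cur]] <= merge_within) {
        if (s[keep[j]] < s[keep[cur]]) cur <- j
      } else {
        merged <- c(merged, cur)
        cur <- j
      }
    }
    merged <- c(merged, cur)
    idx <- keep[unlist(merged)]
    tibble(chrom = ch, start = tt$start[idx], end = tt$end[idx],
           bin_id = tt$bin_id[idx], score = s[idx],
           prominence = prom[match(idx, keep)])
  })
  if (nrow(out) == 0) empty else out
}

# Prominence of a local minimum: smallest rise reached on either side before
# a value below the minimum occurs.
side_prominence <- function(s, i) {
  climb <- function(idx) {
    best <- 0
    for (j in idx) {
      if (s[j] < s[i]) break
      best <- max(best, s[j] - s[i])
    }
    best
  }
  min(climb(rev(seq_len(i - 1))), climb(seq(i + 1, length(s))))
}
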