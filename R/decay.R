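#' Cis contact distance-decay curve
#'
#' Bins cis separations `|pos2 - pos1|` into log10-spaced bins (default 8 per
#' decade starting at `min_dist`) and reports, per group, the contact
#' probability per bin (summing to 1) together with the probability density
#' (`prob / bin width`), whose log-log slope estimates the decay exponent.
#'
#' @param pairs Tibble of contacts (pass unique valid pairs).
#' @param bins_per_decade Log-bin resolution.
#' @param min_dist Smallest separation considered, bp.
#' @param by Optional grouping column (e.g. `"cell_id"` for per-cell decay
#'   profiles); `NULL` pools everything.
#' @return Tibble with `dist_lo`, `dist_hi`, `mid`, `n`, `prob`, `density`
#'   (and the grouping column when `by` is set). No cis pairs yields an empty
#'   curve with a warning.
#' @export
distance_decay <- function(pairs, bins_per_decade = 8, min_dist = 1000,
                           by = NULL) {
  assert_columns(pairs, c("chrom1", "pos1", "chrom2", "pos2"), "pair stream")
  cis <- filter(pairs, .data$chrom1 == .data$chrom2)
  cis$distance <- abs(cis$pos2 - cis$pos1)
  cis <- filter(cis, .data$distance >= min_dist)
  if (nrow(cis) == 0) {
    warn("no cis pairs at or beyond `min_dist`; returning an empty decay curve")
    return(tibble(dist_lo = numeric(0), dist_hi = numeric(0), mid = numeric(0),
                  n = integer(0), prob = numeric(0), density = numeric(0)))
  }
  edges <- 10^seq(log10(min_dist),
                  ceiling(log10(max(cis$distance)) * bins_per_decade) / bins_per_decade,
                  by = 1 / bins_per_decade)
  if (max(edges) <= max(cis$distance)) edges <- c(edges, max(cis$distance) + 1)
  cis$bin <- findInterval(cis$distance, edges, rightmost.closed = TRUE)

  grouping <- c(by, "bin")
  out <- cis |>
    group_by(dplyr::across(dplyr::all_of(grouping))) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(prob = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(dist_lo = edges[.data$bin],
           dist_hi = edges[.data$bin + 1],
           mid = sqrt(.data$dist_lo * .data$dist_hi),
           density = .data$prob / (.data$dist_hi - .data$dist_lo)) |>
    select(dplyr::all_of(by), "dist_lo", "dist_hi", "mid", "n", "prob", "density")
  out
}

#' Fit the decay exponent from a decay curve
#'
#' Ordinary least squares of `log10(density)` on `log10(mid)` over a distance
#' window, returning the slope (for a power law `P(s) ~ s^-alpha` the slope
#' estimates `-alpha`).
#'
#' @param curve Output of [distance_decay()] (one group).
#' @param fit_range Distance window used for the regression, bp.
#' @return Slope (double).
#' @export
decay_slope <- function(curve, fit_range = c(3e3, 2e6)) {
  cc <- filter(curve, .data$mid >= fit_range[1], .data$mid <= fit_range[2],
               .data$n > 0)
  if (nrow(cc) < 3) abort("not enough populated bins in `fit_range`")
  unname(coef(stats::lm(log10(density) ~ log10(mid), data = cc))[2])
}

#' Downsample pairs without replacement
#'
#' Uniform, seed-deterministic subsample of `n` rows (row order preserved).
#' Requesting more than available is an error, matching the convention of
#' only comparing cells whose depth exceeds the threshold.
#'
#' @param pairs Tibble of pairs.
#' @param n Sample size.
#' @param seed Seed.
#' @return Tibble with `n` rows.
#' @export
downsample_pairs <- function(pairs, n, seed = 1) {
  if (n > nrow(pairs)) {
    abort(sprintf("cannot downsample %d pairs to %d; depth below threshold",
                  nrow(pairs), n), class = "schickit_threshold_error")
  }
  idx <- with_seed(seed, sample.int(nrow(pairs), n))
  pairs[sort(idx), , drop = FALSE]
}

#' Fit a library-complexity saturation curve
#'
#' Fits the hyperbolic saturation model `Y = Bmax * X / (Kd + X)` relating
#' unique valid pairs `Y` to sequencing depth `X` by constrained least
#' squares (initialized at `Bmax = 2 max(Y)`, `Kd = median(X)`). `Bmax` is
#' the saturation point (asymptotic library complexity) and `Kd` the depth at
#' half saturation; the fitted curve is monotone non-decreasing by
#' construction.
#'
#' @param data Tibble of observations.
#' @param depth_col,yield_col Column names of depth `X` and unique yield `Y`.
#' @return A `saturation_fit` object; see [tidy()] / [glance()] methods.
#' @examples
#' depths <- c(15.625e3, 31.25e3, 62.5e3, 125e3, 250e3, 500e3, 1e6, 2e6, 4e6)
#' obs <- tibble::tibble(depth = depths,
#'                       unique_valid_pairs = 1e6 * depths / (2e5 + depths))
#' glance(saturation_fit(obs))
#' @export
saturation_fit <- function(data, depth_col = "depth",
                           yield_col = "unique_valid_pairs") {
  assert_columns(data, c(depth_col, yield_col), "saturation observations")
  X <- data[[depth_col]]; Y <- data[[yield_col]]
  if (length(unique(X)) < 3) abort("need at least 3 distinct depths")
  if (all(Y == 0)) abort("degenerate data: all yields are zero")
  df <- tibble(X = X, Y = Y)
  fit <- minpack.lm::nlsLM(
    Y ~ Bmax * X / (Kd + X), data = df,
    start = list(Bmax = 2 * max(Y), Kd = median(X)),
    lower = c(Bmax = .Machine$double.eps, Kd = .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  structure(list(fit = fit, data = df,
                 bmax = unname(est["Bmax"]), kd = unname(est["Kd"])),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> Bmax = %.4g (saturation point), Kd = %.4g\n",
              x$bmax, x$kd))
  invisible(x)
}

#' @export
predict.saturation_fit <- function(object, depth, ...) {
  object$bmax * depth / (object$kd + depth)
}

#' @exportS3Method generics::tidy
tidy.saturation_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @exportS3Method generics::glance
glance.saturation_fit <- function(x, ...) {
  res <- stats::resid(x$fit)
  tibble(bmax = x$bmax, kd = x$kd,
         sigma = sqrt(mean(res^2)), n = nrow(x$data))
}

#' Non-zero coverage fraction across bin sizes and depth thresholds
#'
#' For each cell whose unique valid pairs meet a depth threshold, the cell is
#' downsampled to exactly that threshold and the fraction of non-mito genomic
#' bins touched by at least one contact endpoint (two endpoints per pair) is
#' reported — the per-cell genomic coverage panel.
#'
#' @param pairs Unique valid pairs with `cell_id`.
#' @param genome Genome or chromosome table (mito bins are excluded from the
#'   denominator).
#' @param bin_sizes Bin sizes in bp.
#' @param thresholds Depth thresholds (pairs per cell).
#' @param seed Seed for the per-cell downsampling.
#' @return Tibble `cell_id`, `threshold`, `bin_size`, `covered_bins`,
#'   `total_bins`, `fraction`.
#' @export
coverage_fraction <- function(pairs, genome,
                              bin_sizes = c(5e3, 10e3, 25e3, 50e3),
                              thresholds = c(62.5e3, 125e3, 250e3, 500e3),
                              seed = 1) {
  assert_columns(pairs, c("cell_id", "chrom1", "pos1", "chrom2", "pos2"),
                 "pair stream")
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  if (!"class" %in% names(sizes)) sizes$class <- "autosome"
  nuc <- filter(sizes, .data$class != "mito")
  lens <- setNames(nuc$length, nuc$chrom)

  cells <- split(pairs, pairs$cell_id)
  purrr::map_dfr(seq_along(thresholds), function(ti) {
    thr <- thresholds[ti]
    purrr::map_dfr(names(cells), function(cid) {
      cp <- cells[[cid]]
      if (nrow(cp) < thr) return(tibble())
      cp <- downsample_pairs(cp, thr, seed = derive_seed(seed, paste(cid, thr)))
      ends <- tibble(chrom = c(cp$chrom1, cp$chrom2), pos = c(cp$pos1, cp$pos2))
      ends <- filter(ends, .data$chrom %in% names(lens))
      purrr::map_dfr(bin_sizes, function(bs) {
        total <- sum(ceiling(lens / bs))
        covered <- dplyr::n_distinct(paste(ends$chrom, floor((ends$pos - 1) / bs)))
        tibble(cell_id = cid, threshold = thr, bin_size = bs,
               covered_bins = covered, total_bins = total,
               fraction = covered / total)
      })
    })
  })
}
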