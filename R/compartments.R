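#' A/B compartment eigenvector (compartment score)
#'
#' Per chromosome: the balanced cis matrix is distance-normalized into an
#' observed/expected matrix (expected = mean count per diagonal over
#' unmasked bins), the Pearson correlation matrix of its columns is formed,
#' and the eigenvector of the largest-magnitude eigenvalue is reported as
#' the compartment score (unit Euclidean norm per chromosome). The sign is
#' oriented so the track correlates positively with `orientation` (for
#' simulated data the planted "A-ness" track; for real data a user-supplied
#' proxy such as gene density). Masked bins are `NA`; chromosomes with fewer
#' than 10 usable bins are skipped with a warning.
#'
#' @param mat An ICE-balanced `contact_matrix`.
#' @param orientation Tibble `chrom`, `start`, and an orientation column
#'   (third column or `aness`).
#' @return Tibble `chrom`, `start`, `end`, `bin_id`, `eigen`.
#' @export
compartment_eigenvector <- function(mat, orientation) {
  stopifnot(inherits(mat, "contact_matrix"))
  assert_columns(orientation, c("chrom", "start"), "orientation track")
  ocol <- if ("aness" %in% names(orientation)) "aness" else
    setdiff(names(orientation), c("chrom", "start", "end"))[1]

  purrr::map_dfr(unique(mat$bins$chrom), function(ch) {
    dd <- chrom_dense(mat, ch)
    out <- mutate(dd$bins, eigen = NA_real_)
    n <- nrow(dd$mat)
    usable <- !dd$mask & Matrix::rowSums(dd$mat) > 0
    if (sum(usable) < 10) {
      warn(sprintf("chromosome '%s' has fewer than 10 usable bins; skipped", ch))
      return(out)
    }
    M <- dd$mat[usable, usable, drop = FALSE]
    m <- nrow(M)
    d <- abs(row(M) - col(M))
    expected <- vapply(0:(m - 1), function(k) mean(M[d == k]), numeric(1))
    E <- matrix(expected[d + 1], m, m)
    OE <- ifelse(E > 0, M / E, 0)
    CC <- suppressWarnings(stats::cor(OE))
    CC[!is.finite(CC)] <- 0
    eig <- eigen(CC, symmetric = TRUE)
    lead <- which.max(abs(eig$values))
    v <- eig$vectors[, lead]
    ref <- orientation[orientation$chrom == ch, ]
    ref_val <- ref[[ocol]][match(out$start[usable], ref$start)]
    ok <- !is.na(ref_val)
    if (sum(ok) >= 3 && stats::sd(v[ok]) > 0 && stats::sd(ref_val[ok]) > 0) {
      if (stats::cor(v[ok], ref_val[ok]) < 0) v <- -v
    }
    out$eigen[usable] <- v
    out
  })
}

#' Pearson correlation between two genomic tracks
#'
#' Joins the tracks on `(chrom, start)` and computes the Pearson correlation
#' over jointly non-missing bins. Returns `NA` (with a warning) when either
#' track has zero variance; fewer than 3 shared bins is an error.
#'
#' @param a,b Tibbles with `chrom`, `start` and a value column.
#' @param value_a,value_b Value column names (default: third column).
#' @return Double scalar.
#' @export
track_correlation <- function(a, b, value_a = NULL, value_b = NULL) {
  pick <- function(tb, v) {
    if (!is.null(v)) return(v)
    setdiff(names(tb), c("chrom", "start", "end", "bin_id", "valid"))[1]
  }
  va <- pick(a, value_a); vb <- pick(b, value_b)
  joined <- dplyr::inner_join(
    select(a, "chrom", "start", av = dplyr::all_of(va)),
    select(b, "chrom", "start", bv = dplyr::all_of(vb)),
    by = c("chrom", "start")
  ) |>
    filter(!is.na(.data$av), !is.na(.data$bv))
  if (nrow(joined) < 3) abort("fewer than 3 jointly unmasked bins")
  if (stats::sd(joined$av) == 0 || stats::sd(joined$bv) == 0) {
    warn("zero variance in a track; correlation undefined")
    return(NA_real_)
  }
  stats::cor(joined$av, joined$bv)
}
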