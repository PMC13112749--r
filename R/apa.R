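#' Aggregate peak analysis around loop anchors
#'
#' Averages `(2k+1) x (2k+1)` balanced-count windows centred on loop pixels
#' and scores enrichment as the centre value over the mean of the `c x c`
#' corner at maximal anchor distance (plotted lower-left), the standard
#' background used for loop-strength comparisons. Loops must be cis and at
#' least `k + c` bins away from chromosome edges and from the diagonal;
#' ineligible loops are dropped, and an error listing the exclusions is
#' raised when none survive.
#'
#' @param mat A (preferably ICE-balanced) `contact_matrix`.
#' @param loops Tibble in BEDPE spirit: `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` (anchor midpoints are used).
#' @param half_window Half window size `k` in bins.
#' @param corner Corner size `c` in bins.
#' @return An `apa_result`: list with `window` (the mean matrix, rows =
#'   upstream anchor offset, columns = downstream anchor offset),
#'   `enrichment`, `n_loops`, `excluded`.
#' @export
apa <- function(mat, loops, half_window = 10, corner = 3) {
  stopifnot(inherits(mat, "contact_matrix"))
  assert_columns(loops, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"),
                 "loop list")
  k <- half_window; cs <- corner
  bs <- mat$bin_size
  use_balanced <- !is.null(mat$weights)

  acc <- matrix(0, 2 * k + 1, 2 * k + 1)
  n_used <- 0
  excluded <- character(0)
  dense_cache <- list()

  for (i in seq_len(nrow(loops))) {
    lp <- loops[i, ]
    tag <- sprintf("%s:%d-%s:%d", lp$chrom1, lp$start1, lp$chrom2, lp$start2)
    if (lp$chrom1 != lp$chrom2) { excluded <- c(excluded, paste(tag, "(trans)")); next }
    ch <- lp$chrom1
    if (is.null(dense_cache[[ch]])) {
      dense_cache[[ch]] <- chrom_dense(mat, ch, balanced = use_balanced)
    }
    dd <- dense_cache[[ch]]
    nb <- nrow(dd$mat)
    m1 <- floor(((lp$start1 + lp$end1) / 2) / bs) + 1
    m2 <- floor(((lp$start2 + lp$end2) / 2) / bs) + 1
    if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp }
    if (m1 - k < 1 || m2 + k > nb || (m2 - m1) <= k + cs) {
      excluded <- c(excluded, paste(tag, "(too close to edge or diagonal)"))
      next
    }
    acc <- acc + dd$mat[(m1 - k):(m1 + k), (m2 - k):(m2 + k)]
    n_used <- n_used + 1
  }
  if (n_used == 0) {
    abort(paste0("no eligible loops for APA; excluded: ",
                 paste(excluded, collapse = "; ")))
  }
  win <- acc / n_used
  centre <- win[k + 1, k + 1]
  # maximal-distance background: lowest upstream bin, highest downstream bin
  bg <- mean(win[seq_len(cs), (2 * k + 1 - cs + 1):(2 * k + 1)])
  structure(list(window = win,
                 enrichment = centre / bg,
                 n_loops = n_used,
                 excluded = excluded,
                 half_window = k, corner = cs),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> %d loops, enrichment = %.3f\n",
              x$n_loops, x$enrichment))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.apa_result <- function(x, ...) {
  tibble(enrichment = x$enrichment, n_loops = x$n_loops,
         n_excluded = length(x$excluded))
}
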