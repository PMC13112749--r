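#' Bin contact pairs into a sparse symmetric matrix
#'
#' Each pair increments exactly one upper-triangle cell (`bin1 <= bin2`), so
#' total matrix mass equals the number of input pairs. Bins are half-open
#' genomic windows of `bin_size` bp with globally unique indices across
#' chromosomes.
#'
#' @param pairs Tibble with `chrom1`, `pos1`, `chrom2`, `pos2` (typically
#'   unique valid pairs).
#' @param genome A `toy_genome`, list of them, or a chromosome table
#'   (`chrom`, `length`, and optionally `class`).
#' @param bin_size Bin size in bp (>= 1000).
#' @return A `contact_matrix`: list with `bins` (tibble `chrom`, `start`,
#'   `end`, `bin_id`, `class`), `counts` (tibble `bin1`, `bin2`, `n`),
#'   `bin_size`, and balancing slots (`weights`, `converged`) filled by
#'   [ice_balance()].
#' @examples
#' gn <- toy_genome("alpha", seed = 1)
#' pr <- tibble::tibble(chrom1 = "chrA1", pos1 = 100,
#'                      chrom2 = "chrA1", pos2 = 60000)
#' bin_contacts(pr, gn, bin_size = 50e3)$counts
#' @export
bin_contacts <- function(pairs, genome, bin_size = 50e3) {
  if (bin_size < 1000) abort("`bin_size` must be at least 1 kb")
  assert_columns(pairs, c("chrom1", "pos1", "chrom2", "pos2"), "pair stream")
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  assert_columns(sizes, c("chrom", "length"), "chromosome table")
  if (!"class" %in% names(sizes)) sizes$class <- "autosome"

  bins <- purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    starts <- seq(0, sizes$length[i] - 1, by = bin_size)
    tibble(chrom = sizes$chrom[i], start = starts,
           end = pmin(starts + bin_size, sizes$length[i]),
           class = sizes$class[i])
  })
  bins$bin_id <- seq_len(nrow(bins))
  offsets <- bins |> group_by(.data$chrom) |>
    summarise(off = min(.data$bin_id) - 1L)
  off <- setNames(offsets$off, offsets$chrom)
  lens <- setNames(sizes$length, sizes$chrom)

  for (side in 1:2) {
    ch <- pairs[[paste0("chrom", side)]]
    ps <- pairs[[paste0("pos", side)]]
    if (!all(ch %in% names(lens))) {
      abort("pair chromosome not present in the genome")
    }
    if (any(ps < 1 | ps > lens[ch])) {
      abort("pair position beyond chromosome bounds")
    }
  }

  b1 <- off[pairs$chrom1] + floor((pairs$pos1 - 1) / bin_size) + 1L
  b2 <- off[pairs$chrom2] + floor((pairs$pos2 - 1) / bin_size) + 1L
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  counts <- tibble(bin1 = as.integer(lo), bin2 = as.integer(hi)) |>
    count(.data$bin1, .data$bin2, name = "n")

  structure(list(bins = bins, counts = counts, bin_size = bin_size,
                 weights = NULL, converged = NA, n_iter = NA_integer_),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins (%s bp), %s contacts%s\n",
              nrow(x$bins), format(x$bin_size, big.mark = ","),
              format(sum(x$counts$n), big.mark = ","),
              if (!is.null(x$weights)) ", balanced" else ""))
  invisible(x)
}

contact_sparse <- function(mat, balanced = FALSE) {
  n <- nrow(mat$bins)
  cc <- mat$counts
  x <- as.numeric(cc$n)
  if (balanced) {
    if (is.null(mat$weights)) abort("matrix is not balanced; run ice_balance()")
    x <- x * mat$weights[cc$bin1] * mat$weights[cc$bin2]
    x[is.na(x)] <- 0
  }
  Matrix::sparseMatrix(i = cc$bin1, j = cc$bin2, x = x, dims = c(n, n),
                       symmetric = TRUE)
}

#' Iterative correction (ICE) balancing weights
#'
#' Masks zero-coverage bins plus the lowest `mask_percentile` of non-zero
#' bins, then iterates the multiplicative correction
#' `w_i <- w_i * mean(s) / s_i` on the weighted row sums `s` until their
#' coefficient of variation over unmasked bins falls below `tol`. Balancing
#' is idempotent: re-balancing an already balanced matrix converges in one
#' step, and scaling all counts leaves the normalized balanced matrix
#' unchanged.
#'
#' @param mat A [bin_contacts()] matrix.
#' @param max_iter Iteration budget.
#' @param tol Target coefficient of variation of unmasked row sums.
#' @param mask_percentile Fraction of lowest-coverage non-zero bins to mask.
#' @return `mat` with `weights` (NA on masked bins, mean 1 on unmasked),
#'   `converged` and `n_iter` filled in. Non-convergence returns the last
#'   weights with `converged = FALSE` and a warning.
#' @export
ice_balance <- function(mat, max_iter = 200, tol = 1e-5, mask_percentile = 0.02) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (nrow(mat$counts) == 0) abort("empty contact matrix cannot be balanced")
  A <- contact_sparse(mat)
  n <- nrow(A)
  cov <- Matrix::rowSums(A)
  masked <- cov == 0
  if (mask_percentile > 0 && any(!masked)) {
    cut <- quantile(cov[!masked], mask_percentile)
    masked <- masked | cov < cut  # strictly below: an all-equal matrix masks nothing
  }
  w <- as.numeric(!masked)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    s <- w * as.numeric(A %*% w)
    su <- s[!masked]
    if (length(su) == 0) break
    m <- mean(su)
    if (m == 0) break
    cv <- stats::sd(su) / m
    if (is.na(cv)) cv <- 0
    if (cv < tol) { converged <- TRUE; break }
    upd <- rep(1, n)
    upd[!masked] <- su / m
    upd[upd == 0] <- 1
    w <- w / upd
  }
  if (!converged && it >= max_iter) {
    warn(sprintf("ICE did not reach CV < %g in %d iterations", tol, max_iter))
  }
  # normalize weights to mean 1 on unmasked bins (pure fixed point for an
  # already balanced matrix)
  mw <- mean(w[!masked])
  if (is.finite(mw) && mw > 0) w <- w / mw
  w[masked] <- NA_real_
  mat$weights <- w
  mat$mask <- masked
  mat$converged <- converged
  mat$n_iter <- it
  mat
}

#' Balanced (or raw) counts as a tidy table
#'
#' @param mat A `contact_matrix`.
#' @return The `counts` tibble with a `balanced` column when weights exist.
#' @export
contact_counts <- function(mat) {
  cc <- mat$counts
  if (!is.null(mat$weights)) {
    cc$balanced <- cc$n * mat$weights[cc$bin1] * mat$weights[cc$bin2]
  }
  cc
}

# Dense symmetric matrix of one chromosome (balanced when weights exist).
# Masked bins are zero in the matrix and TRUE in `mask`.
chrom_dense <- function(mat, chrom, balanced = !is.null(mat$weights)) {
  bins <- filter(mat$bins, .data$chrom == !!chrom)
  if (nrow(bins) == 0) abort(sprintf("chromosome '%s' not in matrix", chrom))
  idx <- range(bins$bin_id)
  cc <- filter(mat$counts, .data$bin1 >= idx[1], .data$bin1 <= idx[2],
               .data$bin2 >= idx[1], .data$bin2 <= idx[2])
  n <- nrow(bins)
  M <- matrix(0, n, n)
  i <- cc$bin1 - idx[1] + 1L
  j <- cc$bin2 - idx[1] + 1L
  x <- as.numeric(cc$n)
  if (balanced) {
    w <- mat$weights[cc$bin1] * mat$weights[cc$bin2]
    x <- ifelse(is.na(w), 0, x * w)
  }
  M[cbind(i, j)] <- x
  M[cbind(j, i)] <- x
  mask <- if (!is.null(mat$weights)) is.na(mat$weights[bins$bin_id]) else rep(FALSE, n)
  list(mat = M, mask = mask, bins = bins)
}
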