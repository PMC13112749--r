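#' Generate a motif-avoiding barcode whitelist
#'
#' Draws `n_codes` distinct codes of length `code_length` by seeded rejection
#' sampling. Codes never contain the restriction motif (default `GATC`, which
#' would otherwise be a substrate for the methylation-based enrichment
#' chemistry) and satisfy a minimum pairwise Hamming distance. The request
#' fails with a capacity error naming the binding constraint when it cannot
#' be satisfied within a bounded number of attempts (e.g. 384 six-mers at
#' distance 3 exceed the quaternary sphere-packing bound of ~215 codes).
#'
#' @param n_codes Number of codes requested.
#' @param code_length Code length in bases.
#' @param min_distance Minimum pairwise Hamming distance.
#' @param seed Seed for the rejection sampler.
#' @param forbidden_motif Substring that no code may contain.
#' @param max_attempts Attempt budget before declaring the request infeasible.
#' @return Character vector of `n_codes` codes.
#' @examples
#' wl <- generate_whitelist(96, 6, min_distance = 2, seed = 1)
#' any(grepl("GATC", wl))
#' @export
generate_whitelist <- function(n_codes, code_length, min_distance = 2,
                               seed = 1, forbidden_motif = "GATC",
                               max_attempts = 200 * n_codes + 10000) {
  stopifnot(n_codes >= 1, code_length >= 1, min_distance >= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    codes <- character(0)
    code_mat <- matrix(character(0), nrow = 0, ncol = code_length)
    attempts <- 0
    while (length(codes) < n_codes) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        abort(sprintf(paste0(
          "cannot build %d codes of length %d at Hamming distance >= %d ",
          "avoiding '%s' within %d attempts; the distance/length constraint ",
          "is binding (got %d codes)"),
          n_codes, code_length, min_distance, forbidden_motif,
          max_attempts, length(codes)), class = "schickit_capacity_error")
      }
      cand <- sample(bases, code_length, replace = TRUE)
      cand_str <- paste(cand, collapse = "")
      if (grepl(forbidden_motif, cand_str, fixed = TRUE)) next
      if (nrow(code_mat) > 0) {
        dists <- rowSums(code_mat != matrix(cand, nrow = nrow(code_mat),
                                            ncol = code_length, byrow = TRUE))
        if (any(dists < min_distance)) next
      }
      codes <- c(codes, cand_str)
      code_mat <- rbind(code_mat, cand)
    }
    codes
  })
}

#' Combinatorial barcode capacity of a two-round scheme
#'
#' @param round1,round2 Whitelists (character vectors) or their sizes.
#' @return `length(round1) * length(round2)` as a number
#'   (e.g. 384 x 384 = 147,456).
#' @examples
#' combination_capacity(384, 384)
#' @export
combination_capacity <- function(round1, round2) {
  n1 <- if (is.numeric(round1)) round1 else length(round1)
  n2 <- if (is.numeric(round2)) round2 else length(round2)
  n1 * n2
}

#' Assign an observed barcode sequence to a whitelist code
#'
#' Returns the index of the unique code within `max_mismatch` Hamming
#' distance, or `NA` when no code is close enough or when two codes tie at
#' the minimum distance (ties are never broken arbitrarily, so collision-rate
#' estimates are not inflated by mis-assignment).
#'
#' @param observed Character vector of observed sequences.
#' @param codes Whitelist.
#' @param max_mismatch Maximum tolerated mismatches.
#' @return Integer vector of code indices (`NA` = unassigned).
#' @export
assign_barcode <- function(observed, codes, max_mismatch = 1) {
  code_len <- unique(nchar(codes))
  if (length(code_len) != 1) abort("whitelist codes must share one length")
  if (any(nchar(observed) != code_len)) {
    abort("observed sequences must match the code length")
  }
  code_mat <- do.call(rbind, strsplit(codes, ""))
  vapply(observed, function(seqc) {
    obs <- strsplit(seqc, "")[[1]]
    d <- rowSums(code_mat != matrix(obs, nrow = nrow(code_mat),
                                    ncol = code_len, byrow = TRUE))
    dmin <- min(d)
    if (dmin > max_mismatch || sum(d == dmin) > 1) NA_integer_ else which.min(d)
  }, integer(1), USE.NAMES = FALSE)
}

#' Demultiplex a pair stream by two-round barcodes
#'
#' Assigns every pair carrying raw barcode sequence fields (`bc1_seq`,
#' `bc2_seq`) to a cell identifier, or counts it as unassigned. Assignment is
#' a partition: each pair lands in exactly one cell or in the unassigned
#' bucket, and assigned + unassigned equals the input row count. Unique
#' observed sequences are resolved once and joined back, so cost scales with
#' the number of distinct barcodes, not reads.
#'
#' @param pairs Tibble with `bc1_seq` and `bc2_seq` columns.
#' @param round1,round2 Whitelists for the two rounds.
#' @param max_mismatch Maximum mismatches per round.
#' @return List with `pairs` (assigned rows, with `bc1`, `bc2` indices and a
#'   `cell_id`) and `summary` (tibble with `assigned` and `unassigned`
#'   counts).
#' @export
demultiplex <- function(pairs, round1, round2, max_mismatch = 1) {
  assert_columns(pairs, c("bc1_seq", "bc2_seq"), "pair stream")
  lut <- function(seqs, codes) {
    u <- unique(seqs)
    ok <- !is.na(u) & nchar(u) == unique(nchar(codes))[1]
    idx <- rep(NA_integer_, length(u))
    idx[ok] <- assign_barcode(u[ok], codes, max_mismatch)
    setNames(idx, u)
  }
  i1 <- unname(lut(pairs$bc1_seq, round1)[pairs$bc1_seq])
  i2 <- unname(lut(pairs$bc2_seq, round2)[pairs$bc2_seq])
  assigned <- !is.na(i1) & !is.na(i2)
  out <- pairs[assigned, , drop = FALSE]
  out$bc1 <- i1[assigned]
  out$bc2 <- i2[assigned]
  out$cell_id <- sprintf("BC%03d.%03d", out$bc1, out$bc2)
  n_assigned <- sum(assigned)
  list(pairs = as_tibble(out),
       summary = tibble(assigned = n_assigned,
                        unassigned = nrow(pairs) - n_assigned,
                        total = nrow(pairs)))
}

#' Attach (optionally error-mutated) barcode reads to simulated pairs
#'
#' Turns the simulator's barcode indices into raw sequence fields using the
#' given whitelists, flipping each base independently with probability
#' `error_rate` — the input fixture for demultiplexing tests.
#'
#' @param pairs Simulated pairs with `bc1`, `bc2` index columns.
#' @param round1,round2 Whitelists.
#' @param error_rate Per-base substitution probability.
#' @param seed Seed for the mutation draw.
#' @return `pairs` with `bc1_seq`, `bc2_seq` columns added.
#' @export
attach_barcode_reads <- function(pairs, round1, round2, error_rate = 0, seed = 1) {
  assert_columns(pairs, c("bc1", "bc2"), "pair stream")
  if (max(pairs$bc1) > length(round1) || max(pairs$bc2) > length(round2)) {
    abort("barcode indices exceed whitelist size")
  }
  mutate_seq <- function(seqs) {
    if (error_rate <= 0) return(seqs)
    mat <- do.call(rbind, strsplit(seqs, ""))
    hit <- matrix(runif(length(mat)) < error_rate, nrow = nrow(mat))
    if (any(hit)) {
      repl <- vapply(mat[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
      mat[hit] <- repl
    }
    apply(mat, 1, paste, collapse = "")
  }
  with_seed(seed, {
    pairs$bc1_seq <- mutate_seq(round1[pairs$bc1])
    pairs$bc2_seq <- mutate_seq(round2[pairs$bc2])
    pairs
  })
}
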