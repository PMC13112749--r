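# Shared fixtures: small genomes and clean (artifact-free) simulator
# configurations, plus tiny independent oracles used across files.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# 20-Mb single-autosome genome (plus the obligatory mito) for state and
# track tests; chromosome-level depth of d pairs corresponds to a
# genome-wide depth of roughly d * 3.1e9 / 20e6 in a mammalian genome.
single_chrom_genome <- function(seed = 1) {
  toy_genome("alpha",
             chromosomes = tibble(chrom = c("chrA1", "chrM"),
                                  length = c(20e6, 16e3),
                                  class = c("autosome", "mito")),
             seed = seed)
}

# Simulator config with artifacts, duplicates and mito false positives
# switched off by default: every emitted pair is a clean valid contact.
# Explicit arguments override the clean defaults.
clean_sim_config <- function(...) {
  defaults <- list(artifact_fractions = c(dangling_end = 0, self_circle = 0,
                                          religation = 0),
                   dumped_fraction = 0, duplicate_rate = 0, mito_fp_rate = 0,
                   n_background_barcodes = 0, doublet_rate = 0,
                   pairs_per_cell_sdlog = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

unique_valid <- function(cls) {
  dplyr::filter(cls, .data$category == "valid", !.data$duplicate)
}

# Adjusted Rand index between two label vectors (independent implementation
# cross-checked against mclust in test-melting.R).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Build a contact_matrix object directly from a dense symmetric matrix
# (one synthetic chromosome), for track-level oracles.
dense_to_matrix <- function(M, bin_size = 50e3, chrom = "chrT") {
  n <- nrow(M)
  bins <- tibble(chrom = chrom, start = (0:(n - 1)) * bin_size,
                 end = (1:n) * bin_size, class = "autosome",
                 bin_id = 1:n)
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  counts <- tibble(bin1 = idx[, 1], bin2 = idx[, 2],
                   n = M[idx])
  structure(list(bins = bins, counts = counts, bin_size = bin_size,
                 weights = NULL, converged = NA, n_iter = NA_integer_),
            class = "contact_matrix")
}

# Nested-loop insulation oracle: diamond means, per-window z-scores over
# full-window bins, averaged across window sizes.
insulation_oracle <- function(M, windows) {
  n <- nrow(M)
  wmax <- max(windows)
  zmat <- matrix(NA_real_, n, length(windows))
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    dm <- rep(NA_real_, n)
    for (i in (w + 1):(n - w)) {
      acc <- 0
      for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) acc <- acc + M[a, b]
      dm[i] <- acc / (w * w)
    }
    mu <- mean(dm, na.rm = TRUE); sg <- sd(dm, na.rm = TRUE)
    zmat[, wi] <- (dm - mu) / sg
  }
  score <- rowMeans(zmat)
  score[seq_len(n) <= wmax | seq_len(n) > n - wmax] <- NA_real_
  score
}
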