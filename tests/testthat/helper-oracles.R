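# Independent oracles shared across test files. Each is written from the
# definition, deliberately avoiding the package's own code paths.

# A 10-fragment toy chromosome with cut sites every 100 bp, built from a
# planted sequence so fragment arithmetic is exact.
make_ten_fragment_map <- function() {
  testthat::skip_if_not_installed("Biostrings")
  base <- rep("A", 1000)
  for (cut in seq(100, 900, by = 100)) {
    base[(cut + 1):(cut + 4)] <- c("G", "A", "T", "C")
  }
  ss <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(ss) <- "chrT"
  digest_genome(ss)
}

# Independent HiC-Pro-convention rule table on raw (un-canonicalized) mates.
classify_oracle <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                            f1, f2, mapq1, mapq2, min_mapq = 10) {
  if (mapq1 < min_mapq || mapq2 < min_mapq) return(c("dumped", FALSE))
  if (chrom2 < chrom1 || (chrom1 == chrom2 && pos2 < pos1)) {
    tmp_c <- chrom1; tmp_p <- pos1; tmp_s <- strand1; tmp_f <- f1
    chrom1 <- chrom2; pos1 <- pos2; strand1 <- strand2; f1 <- f2
    chrom2 <- tmp_c; pos2 <- tmp_p; strand2 <- tmp_s; f2 <- tmp_f
  }
  if (chrom1 != chrom2) return(c("valid", TRUE))
  if (f1 == f2) {
    if (strand1 == "+" && strand2 == "-") return(c("dangling_end", TRUE))
    if (strand1 == "-" && strand2 == "+") return(c("self_circle", TRUE))
    return(c("dumped", TRUE))
  }
  if (abs(f1 - f2) == 1 && strand1 == "+" && strand2 == "-") {
    return(c("religation", TRUE))
  }
  c("valid", TRUE)
}

# Planted checkerboard contact matrix: Poisson counts around a power-law
# decay modulated up for same-compartment bin pairs.
make_checkerboard <- function(n_bins = 200, block = 20, depth = 100,
                              contrast = 1, seed = 77) {
  set.seed(seed)
  lab <- ifelse(((seq_len(n_bins) - 1) %/% block) %% 2 == 0, 1, -1)
  M <- matrix(0, n_bins, n_bins)
  for (i in seq_len(n_bins)) {
    for (j in i:n_bins) {
      d <- max(1, j - i)
      mu <- depth / d * (1 + contrast * (lab[i] == lab[j]))
      M[i, j] <- M[j, i] <- rpois(1, mu)
    }
  }
  list(mat = dense_to_matrix(M), labels = lab)
}

# One-sided KS brute-force oracle: ECDF difference at every pooled point by
# plain counting.
ks_oracle <- function(a, b) {
  grid <- sort(c(a, b))
  dmax <- 0
  for (x in grid) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    if (fa - fb > dmax) dmax <- fa - fb
  }
  dmax
}
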