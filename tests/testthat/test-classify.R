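test_that("digest arithmetic matches the single-site example", {
  skip_if_not_installed("Biostrings")
  ss <- Biostrings::DNAStringSet(c(one = "AAAGATCAAA", flat = "AAAAAAAA"))
  fm <- digest_genome(ss, motif = "GATC", cut_offset = 0)
  f1 <- fm$fragments[fm$fragments$chrom == "one", ]
  expect_equal(f1$start, c(0, 3))
  expect_equal(f1$end, c(3, 10))
  # motif-free chromosome: one spanning fragment
  f2 <- fm$fragments[fm$fragments$chrom == "flat", ]
  expect_equal(nrow(f2), 1L)
  expect_equal(c(f2$start, f2$end), c(0, 8))
})

test_that("classification agrees with a brute-force oracle over all configurations", {
  fm <- make_ten_fragment_map()
  cases <- expand.grid(frag = 3:7, offset = -2:2,
                       s1 = c("+", "-"), s2 = c("+", "-"),
                       low_mapq = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  pairs <- tibble(
    cell_id = "c1",
    chrom1 = "chrT", pos1 = cases$frag * 100 - 50, strand1 = cases$s1,
    chrom2 = "chrT", pos2 = (cases$frag + cases$offset) * 100 - 50,
    strand2 = cases$s2,
    mapq1 = ifelse(cases$low_mapq, 5L, 60L), mapq2 = 60L
  )
  got <- classify_pairs(pairs, fm)
  frag_of <- function(pos) floor((pos - 1) / 100) + 1
  for (i in seq_len(nrow(cases))) {
    exp_i <- classify_oracle(
      pairs$chrom1[i], pairs$pos1[i], pairs$strand1[i],
      pairs$chrom2[i], pairs$pos2[i], pairs$strand2[i],
      frag_of(pairs$pos1[i]), frag_of(pairs$pos2[i]),
      pairs$mapq1[i], pairs$mapq2[i]
    )
    expect_equal(got$category[i], exp_i[1])
    expect_equal(got$reported[i], as.logical(exp_i[2]))
  }
})

test_that("classification is invariant to swapping the mates", {
  fm <- make_ten_fragment_map()
  pr <- tibble(cell_id = "c", chrom1 = "chrT", pos1 = c(250, 450, 820),
               strand1 = c("+", "-", "+"),
               chrom2 = "chrT", pos2 = c(255, 260, 120),
               strand2 = c("-", "+", "-"), mapq1 = 60L, mapq2 = 60L)
  swapped <- dplyr::rename(pr, chrom1 = chrom2, chrom2 = chrom1,
                           pos1 = pos2, pos2 = pos1,
                           strand1 = strand2, strand2 = strand1)
  a <- classify_pairs(pr, fm)
  b <- classify_pairs(swapped, fm)
  expect_equal(a$category, b$category)
  expect_equal(a$pos1, b$pos1)
})

test_that("fragment lookup agrees with a linear-scan oracle", {
  gn <- toy_genome("alpha", seed = 6)
  fm <- digest_genome(gn)
  set.seed(1)
  chroms <- sample(gn$chromosomes$chrom, 10000, replace = TRUE,
                   prob = gn$chromosomes$length)
  lens <- setNames(gn$chromosomes$length, gn$chromosomes$chrom)
  pos <- 1 + floor(runif(10000) * lens[chroms])
  got <- lookup_fragment(fm, chroms, pos)
  frags <- fm$fragments
  check <- sample.int(10000, 300)  # linear scan is slow; spot-check a subset
  for (i in check) {
    hit <- which(frags$chrom == chroms[i] & frags$start < pos[i] &
                   frags$end >= pos[i])
    expect_equal(got[i], frags$frag_id[hit])
  }
  expect_error(lookup_fragment(fm, "chrA1", 1e9), "beyond")
})

test_that("explicit duplicates are flagged by first-occurrence order", {
  fm <- make_ten_fragment_map()
  one <- tibble(cell_id = "c", chrom1 = "chrT", pos1 = 150, strand1 = "+",
                chrom2 = "chrT", pos2 = 750, strand2 = "-",
                mapq1 = 60L, mapq2 = 60L)
  trip <- dplyr::bind_rows(one, one, one)
  dd <- deduplicate(classify_pairs(trip, fm))
  expect_equal(dd$duplicate, c(FALSE, TRUE, TRUE))
  # same coordinates in a different cell are not duplicates
  other <- dplyr::mutate(trip, cell_id = c("c", "d", "d"))
  dd2 <- deduplicate(classify_pairs(other, fm))
  expect_equal(dd2$duplicate, c(FALSE, FALSE, TRUE))
})

test_that("the planted duplicate rate is recovered within binomial noise", {
  ga <- toy_genome("alpha", seed = 1)
  cfg <- sim_config(n_cells = c(alpha = 5), n_background_barcodes = 0,
                    pairs_per_cell = 2000, pairs_per_cell_sdlog = 0,
                    duplicate_rate = 0.3, seed = 13)
  sim <- simulate_cells(ga, cfg)
  cls <- deduplicate(classify_pairs(sim$pairs, digest_genome(ga)))
  n <- nrow(cls)
  expect_lt(abs(mean(cls$duplicate) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("QC ratios follow their definitions on a constructed stream", {
  fm <- make_ten_fragment_map()
  # 100 reported pairs: 50 valid (2 of them duplicates), 30 dangling, 20
  # religation; plus 10 mapq-dumped (not reported)
  mk <- function(n, pos1, pos2, s1, s2, mapq = 60L) {
    stopifnot(n <= 50)
    tibble(cell_id = "c", chrom1 = "chrT", pos1 = pos1 + seq_len(n),
           strand1 = s1, chrom2 = "chrT", pos2 = pos2 + seq_len(n),
           strand2 = s2, mapq1 = mapq, mapq2 = 60L)
  }
  valid <- mk(48, 150, 750, "+", "+")
  dupd <- valid[c(1, 1, 2, 2), ]
  dang <- mk(30, 210, 260, "+", "-")
  reli <- mk(20, 421, 521, "+", "-")
  dump <- mk(10, 150, 750, "+", "+", mapq = 3L)
  cls <- deduplicate(classify_pairs(dplyr::bind_rows(valid[-(1:2), ], dupd,
                                                     dang, reli, dump), fm))
  qc <- cell_qc(cls)
  expect_equal(qc$total_pairs, 110L)
  expect_equal(qc$reported_pairs, 100L)
  expect_equal(qc$valid_pairs, 50L)
  expect_equal(qc$unique_valid_pairs, 48L)
  expect_equal(qc$valid_pair_ratio, 0.5)
  expect_equal(qc$dup_rate, 1 - 48 / 50)
  expect_equal(qc$reported_pair_ratio, 100 / 110)
  # all pairs dumped: ratio missing with a warning
  expect_warning(qc0 <- cell_qc(deduplicate(classify_pairs(
    mk(5, 150, 750, "+", "+", mapq = 2L), fm))), "zero reported")
  expect_true(is.na(qc0$valid_pair_ratio))
})

test_that("category counts partition reported pairs in simulation", {
  ga <- toy_genome("alpha", seed = 1)
  sim <- simulate_cells(ga, sim_config(n_cells = c(alpha = 8),
                                       n_background_barcodes = 0,
                                       pairs_per_cell = 1500, seed = 19))
  cls <- deduplicate(classify_pairs(sim$pairs, digest_genome(ga)))
  reported <- cls[cls$reported, ]
  expect_equal(nrow(reported) + sum(!cls$reported), nrow(cls))
  expect_equal(sum(table(reported$category)), nrow(reported))
})

test_that("the mito-nuclear false-positive rate is recovered and edge-ruled", {
  ga <- toy_genome("alpha", seed = 1)
  cfg <- clean_sim_config(n_cells = c(alpha = 5), pairs_per_cell = 10000,
                          mito_fp_rate = 0.02, seed = 23)
  sim <- simulate_cells(ga, cfg)
  cls <- deduplicate(classify_pairs(sim$pairs, digest_genome(ga)))
  fp <- false_positive_rate(cls, ga)
  pooled <- sum(fp$fp_rate * fp$unique_valid_pairs) / sum(fp$unique_valid_pairs)
  n <- sum(fp$unique_valid_pairs)
  expect_lt(abs(pooled - 0.02), 3 * sqrt(0.02 * 0.98 / n))

  # both ends on the mito genome: a cis-mito contact, not a false positive
  fm <- digest_genome(ga)
  both_mito <- tibble(cell_id = "m", chrom1 = "chrM", pos1 = 100,
                      strand1 = "+", chrom2 = "chrM", pos2 = 9000,
                      strand2 = "+", mapq1 = 60L, mapq2 = 60L)
  qb <- false_positive_rate(deduplicate(classify_pairs(both_mito, fm)), ga)
  expect_equal(qb$fp_rate, 0)
  # a genome without mito cannot define the rate
  no_mito <- tibble(chrom = "c1", length = 1e6, class = "autosome")
  expect_error(false_positive_rate(deduplicate(classify_pairs(both_mito, fm)),
                                   no_mito), "mito")
})
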