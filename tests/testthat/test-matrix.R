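ga <- toy_genome("alpha", seed = 1)

test_that("binning arithmetic, mass conservation, and coarsening consistency", {
  pr <- tibble(chrom1 = "chrA1", pos1 = 100, chrom2 = "chrA1", pos2 = 60000)
  m <- bin_contacts(pr, ga, bin_size = 50e3)
  expect_equal(m$counts$bin1, 1L)
  expect_equal(m$counts$bin2, 2L)
  expect_equal(m$counts$n, 1L)

  sim <- simulate_cells(ga, clean_sim_config(n_cells = c(alpha = 2),
                                             pairs_per_cell = 5000, seed = 3))
  m50 <- bin_contacts(sim$pairs, ga, 50e3)
  expect_equal(sum(m50$counts$n), nrow(sim$pairs))

  # re-binning 50 kb counts to 100 kb equals direct 100 kb binning
  m100 <- bin_contacts(sim$pairs, ga, 100e3)
  map50 <- m50$bins
  map50$coarse <- paste(map50$chrom, floor(map50$start / 100e3))
  key <- setNames(map50$coarse, map50$bin_id)
  re <- m50$counts |>
    dplyr::mutate(c1 = unname(key[as.character(bin1)]),
                  c2 = unname(key[as.character(bin2)]),
                  lo = pmin(c1, c2), hi = pmax(c1, c2)) |>
    dplyr::group_by(lo, hi) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  map100 <- m100$bins
  key100 <- setNames(paste(map100$chrom, floor(map100$start / 100e3)),
                     map100$bin_id)
  direct <- m100$counts |>
    dplyr::mutate(lo = unname(pmin(key100[as.character(bin1)],
                                   key100[as.character(bin2)])),
                  hi = unname(pmax(key100[as.character(bin1)],
                                   key100[as.character(bin2)]))) |>
    dplyr::group_by(lo, hi) |>
    dplyr::summarise(n = sum(n), .groups = "drop")
  expect_equal(dplyr::arrange(re, lo, hi), dplyr::arrange(direct, lo, hi))

  expect_error(bin_contacts(tibble(chrom1 = "chrA1", pos1 = 999e9,
                                   chrom2 = "chrA1", pos2 = 1), ga, 50e3),
               "beyond")
})

test_that("ICE balancing: fixed point, convergence quality, scale invariance", {
  # a matrix with equal row sums is already balanced: weights stay 1
  n <- 20
  M <- matrix(1, n, n)
  mat <- dense_to_matrix(M)
  b <- ice_balance(mat)
  expect_true(b$converged)
  expect_lte(b$n_iter, 1L)
  expect_equal(unname(b$weights), rep(1, n), tolerance = 1e-6)

  # a heterogeneous matrix balances to CV < 1e-4, verified by recomputation
  sim <- simulate_cells(ga, clean_sim_config(n_cells = c(alpha = 1),
                                             pairs_per_cell = 60000, seed = 5))
  mh <- ice_balance(bin_contacts(sim$pairs, ga, 200e3))
  expect_true(mh$converged)
  cc <- contact_counts(mh)
  full <- dplyr::bind_rows(cc, dplyr::rename(cc[cc$bin1 != cc$bin2, ],
                                             bin1 = bin2, bin2 = bin1))
  rows <- tapply(full$balanced, full$bin1, sum)
  rows <- rows[!is.na(rows)]
  expect_lt(sd(rows) / mean(rows), 1e-4)

  # doubling counts leaves the normalized balanced matrix unchanged
  mat2 <- mh
  mat2$counts$n <- mat2$counts$n * 2L
  b2 <- ice_balance(mat2)
  r1 <- contact_counts(mh)$balanced
  r2 <- contact_counts(b2)$balanced
  expect_equal(r2 / sum(r2, na.rm = TRUE), r1 / sum(r1, na.rm = TRUE),
               tolerance = 1e-6)

  # idempotence: balancing the balanced counts converges to unit weights
  mat3 <- mh
  mat3$counts$n <- contact_counts(mh)$balanced
  mat3$counts <- mat3$counts[!is.na(mat3$counts$n), ]
  b3 <- ice_balance(mat3, mask_percentile = 0)
  expect_true(b3$converged)
  expect_lt(stats::sd(b3$weights, na.rm = TRUE), 1e-3)
})

test_that("distance decay is a normalized curve with sane edge cases", {
  pr <- tibble(chrom1 = "chrA1", pos1 = rep(1e6, 50),
               chrom2 = "chrA1", pos2 = rep(1e6 + 40000, 50))
  dc <- distance_decay(pr)
  expect_equal(nrow(dc[dc$n > 0, ]), 1L)
  expect_equal(sum(dc$prob), 1)

  sim <- simulate_cells(ga, clean_sim_config(n_cells = c(alpha = 2),
                                             pairs_per_cell = 4000, seed = 7))
  dc2 <- distance_decay(sim$pairs)
  expect_equal(sum(dc2$prob), 1, tolerance = 1e-12)
  expect_warning(distance_decay(tibble(chrom1 = "a", pos1 = 1,
                                       chrom2 = "b", pos2 = 2)), "no cis")
})

test_that("downsampling is exact, deterministic, and hypergeometric", {
  sim <- simulate_cells(ga, sim_config(n_cells = c(alpha = 3),
                                       n_background_barcodes = 0,
                                       pairs_per_cell = 4000, seed = 9))
  pr <- sim$pairs
  expect_identical(downsample_pairs(pr, nrow(pr), seed = 1), pr)
  d1 <- downsample_pairs(pr, 1000, seed = 5)
  d2 <- downsample_pairs(pr, 1000, seed = 5)
  expect_identical(d1, d2)
  expect_error(downsample_pairs(pr, nrow(pr) + 1),
               class = "schickit_threshold_error")
  # category fractions within 3 sigma hypergeometric of the source
  p0 <- mean(pr$true_category == "valid")
  n <- 1000; N <- nrow(pr)
  sigma <- sqrt(p0 * (1 - p0) / n * (N - n) / (N - 1))
  expect_lt(abs(mean(d1$true_category == "valid") - p0), 3 * sigma)
})

test_that("saturation fitting recovers parameters and matches a two-point solve", {
  depths <- c(15.625e3, 31.25e3, 62.5e3, 125e3, 250e3, 500e3, 1e6, 2e6, 4e6)
  yy <- 1e6 * depths / (2e5 + depths)
  ft <- saturation_fit(tibble(depth = depths, unique_valid_pairs = yy))
  expect_lt(abs(ft$bmax - 1e6) / 1e6, 0.001)
  expect_lt(abs(ft$kd - 2e5) / 2e5, 0.001)
  # closed-form inversion from two noiseless points agrees
  x1 <- depths[2]; y1 <- yy[2]; x2 <- depths[8]; y2 <- yy[8]
  kd_cf <- (y2 - y1) / (y1 / x1 - y2 / x2)
  bmax_cf <- y1 * (kd_cf + x1) / x1
  expect_equal(ft$kd, kd_cf, tolerance = 1e-6)
  expect_equal(ft$bmax, bmax_cf, tolerance = 1e-6)
  # fitted curve is monotone non-decreasing
  grid <- predict(ft, seq(min(depths), max(depths), length.out = 50))
  expect_true(all(diff(grid) >= 0))
  expect_error(saturation_fit(tibble(depth = depths[1:9],
                                     unique_valid_pairs = rep(0, 9))),
               "degenerate")
  expect_error(saturation_fit(tibble(depth = c(1, 1, 1),
                                     unique_valid_pairs = c(1, 2, 3))),
               "distinct")
})

test_that("noisy saturation fits stay within five percent in the median", {
  depths <- c(15.625e3, 31.25e3, 62.5e3, 125e3, 250e3, 500e3, 1e6, 2e6, 4e6)
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    yy <- 1e6 * depths / (2e5 + depths) * exp(rnorm(9, 0, 0.02))
    ft <- saturation_fit(tibble(depth = depths, unique_valid_pairs = yy))
    c(abs(ft$bmax - 1e6) / 1e6, abs(ft$kd - 2e5) / 2e5)
  })
  expect_lte(median(errs[1, ]), 0.05)
  expect_lte(median(errs[2, ]), 0.05)
})

test_that("coverage fractions saturate upward in depth and bin size", {
  sim <- simulate_cells(ga, clean_sim_config(n_cells = c(alpha = 3),
                                             pairs_per_cell = 6000, seed = 13))
  cov <- coverage_fraction(sim$pairs, ga, bin_sizes = c(100e3, 500e3),
                           thresholds = c(1000, 4000), seed = 2)
  wide <- tidyr::pivot_wider(cov, id_cols = c("cell_id", "bin_size"),
                             names_from = "threshold", values_from = "fraction")
  expect_true(all(wide$`4000` >= wide$`1000`))
  byb <- tidyr::pivot_wider(cov, id_cols = c("cell_id", "threshold"),
                            names_from = "bin_size", values_from = "fraction")
  expect_true(all(byb$`5e+05` >= byb$`1e+05`))
  # a cell covering every bin scores exactly 1
  tiny <- tibble(chrom = c("t", "chrM"), length = c(4e5, 16e3),
                 class = c("autosome", "mito"))
  allpairs <- tibble(cell_id = "full", chrom1 = "t",
                     pos1 = seq(1, 4e5, by = 5e4) + 10,
                     chrom2 = "t", pos2 = seq(1, 4e5, by = 5e4) + 20)
  cf <- coverage_fraction(allpairs, tiny, bin_sizes = 1e5, thresholds = 8)
  expect_equal(cf$fraction, 1)
})

test_that("APA scores constants at one and planted enrichment at its factor", {
  n <- 60
  M <- matrix(2, n, n)
  loops <- tibble(chrom1 = "chrT", start1 = 20 * 50e3, end1 = 20 * 50e3 + 1,
                  chrom2 = "chrT", start2 = 40 * 50e3, end2 = 40 * 50e3 + 1)
  a1 <- apa(dense_to_matrix(M), loops, half_window = 5, corner = 2)
  expect_equal(a1$enrichment, 1, tolerance = 1e-12)
  M2 <- M
  M2[21, 41] <- M2[41, 21] <- 10  # 5x background at the loop pixel
  a5 <- apa(dense_to_matrix(M2), loops, half_window = 5, corner = 2)
  expect_equal(a5$enrichment, 5, tolerance = 1e-12)
  # loops too close to the diagonal are excluded, empty set errors
  near <- tibble(chrom1 = "chrT", start1 = 20 * 50e3, end1 = 20 * 50e3 + 1,
                 chrom2 = "chrT", start2 = 22 * 50e3, end2 = 22 * 50e3 + 1)
  expect_error(apa(dense_to_matrix(M), near, half_window = 5, corner = 2),
               "no eligible")
})

test_that("loop-anchored extra contacts enrich the APA centre", {
  loops <- tibble(chrom1 = "chrA1", start1 = seq(3e6, 15e6, 2e6),
                  end1 = seq(3e6, 15e6, 2e6) + 1,
                  chrom2 = "chrA1", start2 = seq(3e6, 15e6, 2e6) + 1.5e6,
                  end2 = seq(3e6, 15e6, 2e6) + 1.5e6 + 1)
  wins <- sapply(1:3, function(s) {
    sim <- simulate_cells(ga, clean_sim_config(n_cells = c(alpha = 1),
                                               pairs_per_cell = 60000,
                                               trans_rate = 0, seed = 100 + s))
    pr <- plant_loop_contacts(sim$pairs, loops, fraction = 0.02, seed = s)
    mat <- bin_contacts(pr, ga, 50e3)
    apa(mat, loops, half_window = 8, corner = 3)$enrichment
  })
  expect_true(all(wins > 1))
})
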