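ga <- toy_genome("alpha", seed = 1)
gb <- toy_genome("beta", seed = 2)

test_that("the simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_cells = c(alpha = 8), n_background_barcodes = 15,
                    pairs_per_cell = 300, seed = 99)
  s1 <- simulate_cells(ga, cfg)
  s2 <- simulate_cells(ga, cfg)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$barcodes, s2$barcodes)
})

test_that("emitted per-barcode totals match the ground truth", {
  cfg <- sim_config(n_cells = c(alpha = 10, beta = 10),
                    n_background_barcodes = 20, pairs_per_cell = 400,
                    doublet_rate = 0.2, seed = 4)
  sim <- simulate_cells(list(ga, gb), cfg)
  emitted <- dplyr::count(sim$pairs, cell_id)
  truth <- sim$barcodes
  m <- dplyr::inner_join(emitted, truth, by = "cell_id")
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$n, m$n_pairs)
  cat_sum <- m$n_valid + m$n_dangling_end + m$n_self_circle +
    m$n_religation + m$n_dumped
  expect_equal(cat_sum, m$n_pairs)
})

test_that("planted artifact fractions are recovered within binomial noise", {
  cfg <- sim_config(n_cells = c(alpha = 10), n_background_barcodes = 0,
                    pairs_per_cell = 2000, pairs_per_cell_sdlog = 0,
                    artifact_fractions = c(dangling_end = 0.2,
                                           self_circle = 0.1, religation = 0.1),
                    dumped_fraction = 0.1, duplicate_rate = 0, seed = 8)
  sim <- simulate_cells(ga, cfg)
  n <- nrow(sim$pairs)
  fr <- table(sim$pairs$true_category) / n
  planted <- c(dangling_end = 0.2, self_circle = 0.1, religation = 0.1,
               dumped = 0.1, valid = 0.5)
  for (cat in names(planted)) {
    p <- planted[[cat]]
    expect_lt(abs(fr[[cat]] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("cross-species doublet counts follow the planted binomial rate", {
  cfg <- sim_config(n_cells = c(alpha = 200, beta = 200),
                    n_background_barcodes = 0, doublet_rate = 0.06,
                    pairs_per_cell = 50, seed = 17)
  sim <- simulate_cells(list(ga, gb), cfg)
  nd <- sum(sim$barcodes$type == "doublet")
  ci <- stats::qbinom(c(0.025, 0.975), 400, 0.06)
  expect_gte(nd, ci[1])
  expect_lte(nd, ci[2])
  mixed <- sim$barcodes$species[sim$barcodes$type == "doublet"]
  expect_true(all(mixed == "alpha+beta"))
})

test_that("unweighted alpha=1 decay realizes a log-log slope of -1", {
  cfg <- clean_sim_config(n_cells = c(alpha = 1), pairs_per_cell = 120000,
                          trans_rate = 0, tad_weight = 1,
                          compartment_weight = 1, decay_shift = 0,
                          phase_effect = 0, decay_exponent = 1, seed = 3)
  sim <- simulate_cells(ga, cfg)
  slope <- decay_slope(distance_decay(sim$pairs))
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("haploid cells avoid the missing sex chromosome entirely", {
  cfg <- sim_config(n_cells = c(alpha = 12), n_background_barcodes = 0,
                    pairs_per_cell = 600,
                    ploidy_fractions = c(diploid = 0, haploid_X = 0.5,
                                         haploid_Y = 0.5),
                    seed = 21)
  sim <- simulate_cells(ga, cfg)
  bx <- sim$barcodes$cell_id[sim$barcodes$ploidy == "haploid_X"]
  by <- sim$barcodes$cell_id[sim$barcodes$ploidy == "haploid_Y"]
  px <- sim$pairs[sim$pairs$cell_id %in% bx, ]
  py <- sim$pairs[sim$pairs$cell_id %in% by, ]
  expect_equal(sum(px$chrom1 == "chrY" | px$chrom2 == "chrY"), 0)
  expect_equal(sum(py$chrom1 == "chrX" | py$chrom2 == "chrX"), 0)
})

test_that("zero duplicate rate yields zero dedup flags on clean pairs", {
  cfg <- clean_sim_config(n_cells = c(alpha = 6), pairs_per_cell = 800,
                          seed = 31)
  sim <- simulate_cells(ga, cfg)
  cls <- deduplicate(classify_pairs(sim$pairs, digest_genome(ga)))
  expect_equal(sum(cls$duplicate), 0)
})

test_that("a doublet species mix absent from the genomes errors", {
  cfg <- sim_config(n_cells = c(alpha = 3, gamma = 2), pairs_per_cell = 50,
                    seed = 1)
  expect_error(simulate_cells(list(ga, gb), cfg), "gamma")
})
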