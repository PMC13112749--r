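ga <- toy_genome("alpha", seed = 1)

test_that("repli-score pseudocount arithmetic is exact", {
  dom <- tibble(chrom = "chrA1", start = c(0, 1e6), end = c(1e6, 2e6),
                class = c("early", "late"))
  # 50 pairs entirely inside early domains: 100 early endpoints
  early_pairs <- tibble(cell_id = "e", chrom1 = "chrA1",
                        pos1 = seq(1e3, 9e5, length.out = 50),
                        chrom2 = "chrA1",
                        pos2 = seq(2e3, 9.5e5, length.out = 50))
  rs <- repli_score(early_pairs, dom)
  expect_equal(rs$n_early, 100L)
  expect_equal(rs$ratio, 101 / 1)
  # 50/50 split: ratio exactly 1
  split_pairs <- tibble(cell_id = "s", chrom1 = "chrA1",
                        pos1 = seq(1e3, 9e5, length.out = 30),
                        chrom2 = "chrA1",
                        pos2 = seq(1e6 + 1e3, 1.9e6, length.out = 30))
  rs2 <- repli_score(split_pairs, dom)
  expect_equal(rs2$ratio, 1)
  # uncovered cell flagged uninformative
  off <- tibble(cell_id = "o", chrom1 = "chrA1", pos1 = 5e6,
                chrom2 = "chrA1", pos2 = 6e6)
  expect_warning(rs3 <- repli_score(off, dom), "no endpoints")
  expect_false(rs3$informative)
})

test_that("a planted phase gradient is recovered by the repli-score ranking", {
  cfg <- clean_sim_config(n_cells = c(alpha = 60), pairs_per_cell = 2500,
                          trans_rate = 0.05, seed = 21)
  sim <- simulate_cells(ga, cfg)
  rs <- repli_score(sim$pairs, sim_repli_domains(ga, cfg))
  m <- dplyr::inner_join(rs, dplyr::select(sim$barcodes, cell_id, phase),
                         by = "cell_id")
  expect_gte(cor(m$phase, m$rank, method = "spearman"), 0.8)
})

test_that("repli ranking is stable under uniform downsampling", {
  cfg <- clean_sim_config(n_cells = c(alpha = 40), pairs_per_cell = 3000,
                          trans_rate = 0.05, seed = 25)
  sim <- simulate_cells(ga, cfg)
  dom <- sim_repli_domains(ga, cfg)
  full <- repli_score(sim$pairs, dom)
  set.seed(1)
  half <- sim$pairs |>
    dplyr::group_by(cell_id) |>
    dplyr::slice_sample(prop = 0.5) |>
    dplyr::ungroup()
  down <- repli_score(half, dom)
  m <- dplyr::inner_join(full, down, by = "cell_id")
  expect_gte(cor(m$rank.x, m$rank.y, method = "spearman"), 0.9)
})

test_that("haploid scores separate ploidy and match the closed form", {
  cfg <- clean_sim_config(n_cells = c(alpha = 60), pairs_per_cell = 2500,
                          trans_rate = 0.05, tad_weight = 1,
                          compartment_weight = 1,
                          ploidy_fractions = c(diploid = 0.5, haploid_X = 0.5,
                                               haploid_Y = 0),
                          seed = 22)
  sim <- simulate_cells(ga, cfg)
  hs <- haploid_score(sim$pairs, ga)
  m <- dplyr::inner_join(hs, dplyr::select(sim$barcodes, cell_id, ploidy),
                         by = "cell_id")
  lx <- 5e6; ly <- 1e6; la <- 35e6
  e_dip <- (lx + ly) / (2 * la + lx + ly)
  expected_hx <- (lx / (la + lx)) / e_dip
  mean_hx <- mean(m$score[m$ploidy == "haploid_X"])
  expect_lt(abs(mean_hx - expected_hx) / expected_hx, 0.05)
  expect_lt(abs(mean(m$score[m$ploidy == "diploid"]) - 1), 0.1)
  # rank separation
  skip_if_not_installed("pROC")
  auc <- as.numeric(pROC::auc(pROC::roc(m$ploidy == "haploid_X", m$score,
                                        quiet = TRUE)))
  expect_gte(auc, 0.95)
  # scale invariance: halving every cell's pairs leaves scores unchanged in
  # expectation; check exact invariance under duplication of the stream
  dbl <- dplyr::bind_rows(sim$pairs, sim$pairs)
  hs2 <- haploid_score(dbl, ga)
  expect_equal(hs2$score, hs$score)
  expect_error(haploid_score(sim$pairs,
                             tibble(chrom = "c", length = 1, class = "autosome")),
               "sex")
})

test_that("group trans/cis comparison: rank-sum statistic matches enumeration", {
  qc <- tibble(cell_id = sprintf("c%02d", 1:8),
               log2_trans_cis = c(1.1, 2.3, 0.7, 3.1, -0.2, 0.1, -1.4, 0.4))
  groups <- tibble(cell_id = qc$cell_id,
                   group = rep(c("haploid", "diploid"), each = 4))
  res <- group_compare_trans_cis(qc, groups)
  # the reported U is referenced to the alphabetically first group (diploid)
  xd <- qc$log2_trans_cis[5:8]; yh <- qc$log2_trans_cis[1:4]
  u_oracle <- sum(outer(xd, yh, ">"))
  # exact two-sided p by enumerating all 8-choose-4 group assignments
  pool <- c(xd, yh)
  combs <- utils::combn(8, 4)
  u_all <- apply(combs, 2, function(ix) {
    sum(outer(pool[ix], pool[-ix], ">"))
  })
  mu <- mean(u_all)
  p_oracle <- mean(abs(u_all - mu) >= abs(u_oracle - mu))
  expect_equal(res$statistic, u_oracle)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  # identical groups: p near 1
  same <- tibble(cell_id = sprintf("d%02d", 1:8),
                 log2_trans_cis = rep(c(1, 2, 3, 4), 2))
  gs <- tibble(cell_id = same$cell_id, group = rep(c("a", "b"), each = 4))
  res0 <- group_compare_trans_cis(same, gs)
  expect_gte(res0$p_value, 0.9)
  # tiny groups: stats without a test
  expect_warning(r2 <- group_compare_trans_cis(qc[c(1, 2, 5, 6), ],
                                               groups[c(1, 2, 5, 6), ]),
                 "fewer than 3")
  expect_true(is.na(r2$p_value))
})

test_that("haploid cells with doubled trans rates show higher trans/cis", {
  wins <- sapply(1:5, function(s) {
    cfg <- clean_sim_config(n_cells = c(alpha = 30), pairs_per_cell = 800,
                            trans_rate = 0.1, trans_rate_haploid = 0.2,
                            ploidy_fractions = c(diploid = 0.5,
                                                 haploid_X = 0.5,
                                                 haploid_Y = 0),
                            seed = 400 + s)
    sim <- simulate_cells(ga, cfg)
    cls <- deduplicate(classify_pairs(sim$pairs, digest_genome(ga)))
    qc <- cell_qc(cls, ga)
    m <- dplyr::inner_join(qc, dplyr::select(sim$barcodes, cell_id, ploidy),
                           by = "cell_id")
    median(m$log2_trans_cis[m$ploidy == "haploid_X"]) >
      median(m$log2_trans_cis[m$ploidy == "diploid"])
  })
  expect_true(all(wins))
})
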