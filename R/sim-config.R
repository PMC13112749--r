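#' Configure the single-cell contact simulator
#'
#' Collects every knob of the synthetic data generator. Defaults describe a
#' desk-scale library that mirrors the structure of a split-pool barnyard
#' experiment: two species of cells, cross-species doublets, low-count
#' background barcodes, HiC-Pro artifact categories at an overall ~50%
#' valid-pair fraction, PCR duplicates, mitochondrial-nuclear false-positive
#' contacts, a power-law cis decay, TAD blocks that differ between a melting
#' and a concretion chromatin state inside a designated region, an A/B
#' compartment checkerboard, and early/late replication-timing domains that
#' couple to a per-cell cell-cycle phase.
#'
#' @param n_cells Named integer vector: cells per species (names must match
#'   simulated genomes).
#' @param doublet_rate Probability that a cell slot holds two cells (cross-
#'   species when two genomes are supplied) under one barcode.
#' @param n_background_barcodes Number of ambient low-count barcodes.
#' @param background_count_meanlog,background_count_sdlog Lognormal parameters
#'   of background barcode pair counts.
#' @param pairs_per_cell,pairs_per_cell_sdlog Lognormal mean / sdlog of the
#'   per-cell target pair count.
#' @param duplicate_rate Fraction of emitted pairs that are PCR re-reads of an
#'   earlier pair of the same cell.
#' @param artifact_fractions Named fractions for `dangling_end`, `self_circle`
#'   and `religation` pairs.
#' @param dumped_fraction Fraction of pairs emitted with sub-threshold mapping
#'   quality (HiC-Pro "dumped" bucket).
#' @param mito_fp_rate Fraction of valid pairs whose second end is relocated to
#'   the mitochondrial chromosome (a mito-nuclear false positive).
#' @param trans_rate Probability that a valid pair is inter-chromosomal.
#' @param trans_rate_haploid Optional trans rate for haploid cells (defaults
#'   to `trans_rate`); haploid spermatids show elevated trans/cis ratios.
#' @param decay_exponent Power-law exponent alpha of the cis contact distance
#'   distribution, density proportional to s^-alpha on `[min_distance, L]`.
#' @param min_distance Shortest cis separation in bp.
#' @param tad_weight Acceptance up-weighting of intra-TAD cis contacts
#'   (1 disables TAD structure).
#' @param tad_spacing Baseline TAD boundary spacing in bp (both states share
#'   these boundaries outside the melting region).
#' @param melting_region List `(chrom, start, end)` of the state-divergent
#'   region: the concretion state carries boundaries every
#'   `concretion_spacing` bp inside it, the melting state none.
#' @param concretion_spacing Boundary spacing inside the melting region for
#'   concretion-state cells.
#' @param compartment_weight Acceptance up-weighting of same-compartment cis
#'   contacts beyond `compartment_min_dist` (1 disables).
#' @param compartment_block_size A/B checkerboard block size in bp.
#' @param compartment_min_dist Minimum separation at which compartment
#'   weighting applies.
#' @param repli_block_size Early/late replication domain block size in bp.
#' @param phase_effect Strength of the cell-cycle coupling: the probability
#'   that a cis anchor falls in an early domain is
#'   `0.5 + phase_effect * (0.5 - phase)`.
#' @param decay_shift Log2 shift of cis distances across the phase gradient
#'   (moves contact mass between short and long range).
#' @param melting_fraction Fraction of cells planted in the melting state.
#' @param ploidy_fractions Named fractions for `diploid`, `haploid_X`,
#'   `haploid_Y` cells.
#' @param seed Seed for the whole simulation.
#' @return A validated `sim_config` object (a list).
#' @examples
#' cfg <- sim_config(n_cells = c(alpha = 20), n_background_barcodes = 50)
#' @export
sim_config <- function(n_cells = c(alpha = 100, beta = 100),
                       doublet_rate = 0.05,
                       n_background_barcodes = 1000,
                       background_count_meanlog = log(30),
                       background_count_sdlog = 0.8,
                       pairs_per_cell = 2000,
                       pairs_per_cell_sdlog = 0.4,
                       duplicate_rate = 0.1,
                       artifact_fractions = c(dangling_end = 0.2,
                                              self_circle = 0.1,
                                              religation = 0.1),
                       dumped_fraction = 0.1,
                       mito_fp_rate = 0.01,
                       trans_rate = 0.1,
                       trans_rate_haploid = NULL,
                       decay_exponent = 1,
                       min_distance = 1000,
                       tad_weight = 4,
                       tad_spacing = 500e3,
                       melting_region = list(chrom = "chrA1",
                                             start = 12e6, end = 15e6),
                       concretion_spacing = 250e3,
                       compartment_weight = 3,
                       compartment_block_size = 2e6,
                       compartment_min_dist = 1e6,
                       repli_block_size = 1e6,
                       phase_effect = 0.6,
                       decay_shift = 1,
                       melting_fraction = 0.5,
                       ploidy_fractions = c(diploid = 1, haploid_X = 0,
                                            haploid_Y = 0),
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  req <- c("dangling_end", "self_circle", "religation")
  if (!all(req %in% names(cfg$artifact_fractions))) {
    abort("`artifact_fractions` must name dangling_end, self_circle, religation")
  }
  fracs <- c(cfg$artifact_fractions[req], dumped = unname(cfg$dumped_fraction))
  if (any(fracs < 0 | fracs > 1)) abort("artifact fractions must lie in [0, 1]")
  valid_frac <- 1 - sum(fracs)
  if (valid_frac < 0) {
    abort("artifact fractions plus the dumped fraction exceed 1; no mass left for valid pairs")
  }
  for (f in c("doublet_rate", "duplicate_rate", "mito_fp_rate", "trans_rate",
              "melting_fraction")) {
    v <- cfg[[f]]
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a fraction in [0, 1]", f))
    }
  }
  if (any(cfg$n_cells < 0) || is.null(names(cfg$n_cells))) {
    abort("`n_cells` must be a named, non-negative vector (one entry per species)")
  }
  if (cfg$pairs_per_cell <= 0) abort("`pairs_per_cell` must be positive")
  if (cfg$decay_exponent <= 0) abort("`decay_exponent` must be positive")
  if (cfg$tad_weight < 1 || cfg$compartment_weight < 1) {
    abort("`tad_weight` and `compartment_weight` must be >= 1")
  }
  pf <- cfg$ploidy_fractions
  if (abs(sum(pf) - 1) > 1e-8) abort("`ploidy_fractions` must sum to 1")
  cfg$valid_fraction <- valid_frac
  cfg
}

#' Planted TAD boundaries of one chromatin state
#'
#' Baseline boundaries are evenly spaced at `tad_spacing` on every non-mito
#' chromosome and are shared by both states. Inside the designated melting
#' region the concretion state carries denser boundaries
#' (`concretion_spacing`) while the melting state carries none.
#'
#' @param genome A `toy_genome` (or list of genomes).
#' @param config A `sim_config`.
#' @param state `"melting"` or `"concretion"`.
#' @return Tibble `chrom`, `pos`, `state`.
#' @export
sim_tad_boundaries <- function(genome, config, state = c("concretion", "melting")) {
  state <- match.arg(state)
  sizes <- chrom_sizes(genome)
  sizes <- filter(sizes, .data$class != "mito")
  mr <- config$melting_region
  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    ch <- sizes$chrom[i]; len <- sizes$length[i]
    pos <- seq(config$tad_spacing, len - config$tad_spacing / 2,
               by = config$tad_spacing)
    if (ch == mr$chrom) {
      inside <- pos > mr$start & pos < mr$end
      pos <- pos[!inside]
      if (state == "concretion") {
        pos <- sort(c(pos, seq(mr$start, mr$end, by = config$concretion_spacing)))
      }
    }
    tibble(chrom = ch, pos = pos, state = state)
  })
}

#' Planted A/B compartment labels per bin ("A-ness" orientation track)
#'
#' @param genome A `toy_genome` or list of genomes.
#' @param config A `sim_config`.
#' @param bin_size Bin size in bp.
#' @return Tibble `chrom`, `start`, `end`, `aness` (+1 for A, -1 for B).
#' @export
sim_compartment_track <- function(genome, config, bin_size = 50e3) {
  sizes <- filter(chrom_sizes(genome), .data$class != "mito")
  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    len <- sizes$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    mid <- pmin(starts + bin_size / 2, len - 1)
    tibble(chrom = sizes$chrom[i],
           start = starts,
           end = pmin(starts + bin_size, len),
           aness = ifelse(compartment_parity(mid, config$compartment_block_size) == 0,
                          1, -1))
  })
}

compartment_parity <- function(pos, block) as.integer(floor(pos / block)) %% 2L

repli_class_of <- function(pos, block) {
  ifelse(as.integer(floor(pos / block)) %% 2L == 0L, "early", "late")
}

#' Planted early/late replication-timing domains
#'
#' @inheritParams sim_compartment_track
#' @return Tibble `chrom`, `start`, `end`, `class` (`early`/`late`).
#' @export
sim_repli_domains <- function(genome, config) {
  sizes <- filter(chrom_sizes(genome), .data$class != "mito")
  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    len <- sizes$length[i]
    starts <- seq(0, len - 1, by = config$repli_block_size)
    tibble(chrom = sizes$chrom[i],
           start = starts,
           end = pmin(starts + config$repli_block_size, len),
           class = repli_class_of(starts, config$repli_block_size))
  })
}
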