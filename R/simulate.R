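#' Simulate barcode-tagged single-cell contact pairs with planted truth
#'
#' Draws a complete synthetic library from one or two toy genomes under a
#' [sim_config()]: real cells (optionally merged into cross-species doublets
#' under a shared barcode), low-count background barcodes, HiC-Pro artifact
#' categories (dangling ends and self-circles at fragment termini, religation
#' pairs on adjacent fragments, sub-mapq "dumped" pairs), PCR duplicates,
#' mito-nuclear false positives, a truncated power-law cis decay with
#' TAD/compartment acceptance weighting per planted chromatin state, and a
#' replication-timing anchor preference tied to each cell's cell-cycle phase.
#' Valid-pair ends are snapped 0-300 bp inside restriction fragments,
#' mimicking sonication after ligation; planted-valid pairs are nudged off
#' same-fragment and adjacent-inward configurations so that the planted
#' category is the one the classifier rule table assigns. The draw is fully
#' deterministic under `config$seed`.
#'
#' @param genomes A `toy_genome` or list of them; names in `config$n_cells`
#'   must match the species tags.
#' @param config A [sim_config()].
#' @return A list with
#'   * `pairs`: tibble of emitted pairs (`read_id`, `cell_id`, `bc1`, `bc2`,
#'     `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`, `mapq1`,
#'     `mapq2`, `species`, `true_category`, `true_duplicate`, `true_mito_fp`);
#'   * `barcodes`: per-barcode ground truth (type, species mix, state, ploidy,
#'     phase, planted category counts).
#' @examples
#' gn <- toy_genome("alpha", seed = 1)
#' cfg <- sim_config(n_cells = c(alpha = 5), n_background_barcodes = 10,
#'                   pairs_per_cell = 200, seed = 7)
#' sim <- simulate_cells(gn, cfg)
#' dplyr::count(sim$pairs, true_category)
#' @export
simulate_cells <- function(genomes, config) {
  genomes <- as_genome_list(genomes)
  stopifnot(inherits(config, "sim_config"))
  tags <- vapply(genomes, function(g) g$species, character(1))
  names(genomes) <- tags
  unknown <- setdiff(names(config$n_cells), tags)
  if (length(unknown) > 0) {
    abort(sprintf("species in `n_cells` not present in genomes: %s",
                  paste(unknown, collapse = ", ")))
  }

  with_seed(config$seed, {
    profiles <- build_profiles(tags, genomes, config)
    slots <- attr(profiles, "slots")
    frag_maps <- lapply(genomes, digest_genome)

    pairs <- purrr::map_dfr(tags, function(sp) {
      pr <- filter(profiles, .data$species == sp, .data$target > 0)
      if (nrow(pr) == 0) return(tibble())
      gen_species_pairs(genomes[[sp]], frag_maps[[sp]], pr, config)
    })

    pairs <- pairs |>
      left_join(select(profiles, "profile_id", "slot_id"), by = "profile_id") |>
      left_join(select(slots, "slot_id", "cell_id", "bc1", "bc2"),
                by = "slot_id") |>
      arrange(.data$slot_id, .data$profile_id)

    pairs <- apply_duplicates(pairs, config$duplicate_rate)
    pairs <- mutate(pairs, read_id = sprintf("r%08d", seq_len(nrow(pairs))),
                    .before = 1)

    truth <- summarise_truth(pairs, profiles, slots)
    pairs <- select(pairs, "read_id", "cell_id", "bc1", "bc2",
                    "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
                    "mapq1", "mapq2", "species", "true_category",
                    "true_duplicate", "true_mito_fp")
    list(pairs = pairs, barcodes = truth)
  })
}

# One slot per barcode; doublet slots hold two profiles (cross-species when
# two genomes are available). Background barcodes are single low-count
# profiles with no planted phase gradient.
build_profiles <- function(tags, genomes, config) {
  n_slots <- sum(config$n_cells)
  slot_species <- rep(names(config$n_cells), config$n_cells)
  is_doublet <- runif(n_slots) < config$doublet_rate

  n_bg <- config$n_background_barcodes
  glens <- vapply(genomes, function(g) sum(g$chromosomes$length), numeric(1))
  bg_species <- if (n_bg > 0) {
    sample(tags, n_bg, replace = TRUE, prob = glens)
  } else character(0)

  slots <- tibble(
    slot_id = seq_len(n_slots + n_bg),
    type = c(ifelse(is_doublet, "doublet", "cell"), rep("background", n_bg))
  )
  combos <- sample.int(384L * 384L, nrow(slots))
  slots$bc1 <- (combos - 1L) %/% 384L + 1L
  slots$bc2 <- (combos - 1L) %% 384L + 1L
  slots$cell_id <- sprintf("BC%03d.%03d", slots$bc1, slots$bc2)

  primary <- tibble(slot_id = seq_len(n_slots), species = slot_species,
                    role = "primary")
  secondary <- primary[is_doublet, , drop = FALSE]
  if (nrow(secondary) > 0) {
    secondary$role <- "secondary"
    if (length(tags) >= 2) {
      secondary$species <- vapply(secondary$species, function(sp) {
        others <- setdiff(tags, sp)
        others[sample.int(length(others), 1L)]
      }, character(1))
    }
  }
  background <- tibble(slot_id = n_slots + seq_len(n_bg),
                       species = bg_species, role = "background")

  profiles <- bind_rows(primary, secondary, background)
  np <- nrow(profiles)
  profiles <- mutate(
    profiles,
    profile_id = seq_len(np),
    state = sample(c("melting", "concretion"), np, replace = TRUE,
                   prob = c(config$melting_fraction, 1 - config$melting_fraction)),
    ploidy = sample(names(config$ploidy_fractions), np, replace = TRUE,
                    prob = config$ploidy_fractions),
    phase = runif(np),
    target = as.integer(pmax(2, round(stats::rlnorm(
      np, meanlog = log(config$pairs_per_cell),
      sdlog = config$pairs_per_cell_sdlog))))
  )
  bg <- profiles$role == "background"
  profiles$phase[bg] <- 0.5
  profiles$ploidy[bg] <- names(config$ploidy_fractions)[1]
  if (any(bg)) {
    profiles$target[bg] <- as.integer(pmax(1, round(stats::rlnorm(
      sum(bg), meanlog = config$background_count_meanlog,
      sdlog = config$background_count_sdlog))))
  }
  attr(profiles, "slots") <- slots
  profiles
}

# Inverse-CDF draw from a truncated power law with density ~ s^-alpha on
# [smin, smax]; smax may vary per draw.
draw_cis_distance <- function(n, alpha, smin, smax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(smin) + u * (log(smax) - log(smin)))
  } else {
    a1 <- 1 - alpha
    (smin^a1 + u * (smax^a1 - smin^a1))^(1 / a1)
  }
}

# Chromosomes a cell of the given ploidy can emit contacts from, with
# sampling weights proportional to copy number x length (an XY diploid holds
# two autosome copies but single X and Y; haploids hold one copy of
# everything they carry).
allowed_chroms <- function(genome, ploidy) {
  tb <- genome$chromosomes
  keep <- tb$class != "mito"
  if (ploidy == "haploid_X") keep <- keep & tb$class != "sex_Y"
  if (ploidy == "haploid_Y") keep <- keep & tb$class != "sex_X"
  tb <- tb[keep, , drop = FALSE]
  copies <- if (ploidy == "diploid") {
    ifelse(tb$class %in% c("sex_X", "sex_Y"), 1, 2)
  } else {
    rep(1, nrow(tb))
  }
  tb$weight <- copies * tb$length
  tb
}

split_boundaries <- function(tb) split(tb$pos, tb$chrom)

p_early_of <- function(phase, effect) {
  pmin(0.98, pmax(0.02, 0.5 + effect * (0.5 - phase)))
}

gen_species_pairs <- function(genome, fmap, profiles, config) {
  n_i <- profiles$target
  N <- sum(n_i)
  prof_row <- rep(seq_len(nrow(profiles)), n_i)
  cats <- c("valid", names(config$artifact_fractions), "dumped")
  probs <- c(config$valid_fraction, unname(config$artifact_fractions),
             config$dumped_fraction)
  category <- sample(cats, N, replace = TRUE, prob = probs)

  out <- tibble(
    profile_id = profiles$profile_id[prof_row],
    chrom1 = NA_character_, pos1 = NA_real_, strand1 = NA_character_,
    chrom2 = NA_character_, pos2 = NA_real_, strand2 = NA_character_,
    mapq1 = 60L, mapq2 = 60L,
    species = genome$species,
    true_category = category,
    true_mito_fp = FALSE
  )

  frags <- fmap$fragments
  frag_len <- pmax(1L, frags$end - frags$start)
  state_row <- profiles$state[prof_row]
  phase_row <- profiles$phase[prof_row]
  ploidy_row <- profiles$ploidy[prof_row]

  boundaries <- list(
    concretion = split_boundaries(sim_tad_boundaries(genome, config, "concretion")),
    melting = split_boundaries(sim_tad_boundaries(genome, config, "melting"))
  )

  iv <- which(category == "valid")
  if (length(iv) > 0) {
    vp <- gen_valid_pairs(genome, fmap, config, state = state_row[iv],
                          phase = phase_row[iv], ploidy = ploidy_row[iv],
                          boundaries = boundaries)
    out$chrom1[iv] <- vp$chrom1; out$pos1[iv] <- vp$pos1
    out$strand1[iv] <- vp$strand1
    out$chrom2[iv] <- vp$chrom2; out$pos2[iv] <- vp$pos2
    out$strand2[iv] <- vp$strand2
    out$true_mito_fp[iv] <- vp$mito_fp
  }

  # artifacts and dumped pairs come from the cell's own DNA: fragment
  # sampling is restricted to the chromosomes the ploidy carries, weighted
  # by copy number
  for (pl in unique(ploidy_row)) {
    tb <- allowed_chroms(genome, pl)
    copy <- setNames(tb$weight / tb$length, tb$chrom)
    pfr <- which(frags$chrom %in% tb$chrom)
    pw <- frag_len[pfr] * copy[frags$chrom[pfr]]

    for (cc in intersect(c("dangling_end", "self_circle"), cats)) {
      ii <- which(category == cc & ploidy_row == pl)
      if (length(ii) == 0) next
      fi <- pfr[sample.int(length(pfr), length(ii), replace = TRUE, prob = pw)]
      out$chrom1[ii] <- frags$chrom[fi]
      out$chrom2[ii] <- frags$chrom[fi]
      out$pos1[ii] <- frags$start[fi] + 1
      out$pos2[ii] <- frags$end[fi]
      if (cc == "dangling_end") {
        out$strand1[ii] <- "+"; out$strand2[ii] <- "-"
      } else {
        out$strand1[ii] <- "-"; out$strand2[ii] <- "+"
      }
    }

    ir <- which(category == "religation" & ploidy_row == pl)
    if (length(ir) > 0) {
      adj <- pfr[frags$chrom[pfr] == frags$chrom[pmin(pfr + 1, nrow(frags))] &
                   pfr < nrow(frags)]
      fi <- adj[sample.int(length(adj), length(ir), replace = TRUE)]
      out$chrom1[ir] <- frags$chrom[fi]
      out$chrom2[ir] <- frags$chrom[fi]
      out$pos1[ir] <- frags$start[fi] + 1 + floor(runif(length(ir)) * frag_len[fi])
      out$pos2[ir] <- frags$start[fi + 1] + 1 +
        floor(runif(length(ir)) * frag_len[fi + 1])
      out$strand1[ir] <- "+"; out$strand2[ir] <- "-"
    }

    idp <- which(category == "dumped" & ploidy_row == pl)
    if (length(idp) > 0) {
      ci <- sample.int(nrow(tb), length(idp), replace = TRUE, prob = tb$weight)
      out$chrom1[idp] <- tb$chrom[ci]; out$chrom2[idp] <- tb$chrom[ci]
      out$pos1[idp] <- 1 + floor(runif(length(idp)) * tb$length[ci])
      out$pos2[idp] <- 1 + floor(runif(length(idp)) * tb$length[ci])
      out$strand1[idp] <- sample(c("+", "-"), length(idp), replace = TRUE)
      out$strand2[idp] <- sample(c("+", "-"), length(idp), replace = TRUE)
      out$mapq1[idp] <- 5L
    }
  }

  out$pos1 <- as.integer(round(out$pos1))
  out$pos2 <- as.integer(round(out$pos2))
  out
}

# Valid (ligation-informative) pairs for one species. Cis separations follow
# the truncated power law; anchors prefer early or late replication domains
# according to the cell's phase; intra-TAD and same-compartment contacts are
# favoured by rejection thinning with redraw (bounded rounds).
gen_valid_pairs <- function(genome, fmap, config, state, phase, ploidy, boundaries) {
  n <- length(state)
  chrom1 <- character(n); chrom2 <- character(n)
  pos1 <- numeric(n); pos2 <- numeric(n)

  for (pl in unique(ploidy)) {
    rows <- which(ploidy == pl)
    tb <- allowed_chroms(genome, pl)
    tr <- if (pl %in% c("haploid_X", "haploid_Y")) {
      config$trans_rate_haploid %||% config$trans_rate
    } else config$trans_rate
    trans <- runif(length(rows)) < tr & nrow(tb) >= 2

    it <- rows[trans]
    if (length(it) > 0) {
      c1 <- sample.int(nrow(tb), length(it), replace = TRUE, prob = tb$weight)
      c2 <- sample.int(nrow(tb), length(it), replace = TRUE, prob = tb$weight)
      same <- which(c1 == c2)
      while (length(same) > 0) {
        c2[same] <- sample.int(nrow(tb), length(same), replace = TRUE,
                               prob = tb$weight)
        same <- same[c1[same] == c2[same]]
      }
      chrom1[it] <- tb$chrom[c1]; chrom2[it] <- tb$chrom[c2]
      pos1[it] <- 1 + floor(runif(length(it)) * tb$length[c1])
      pos2[it] <- 1 + floor(runif(length(it)) * tb$length[c2])
    }

    ic <- rows[!trans]
    if (length(ic) > 0) {
      cis <- gen_cis_pairs(tb, config, state[ic], phase[ic], boundaries)
      chrom1[ic] <- cis$chrom; chrom2[ic] <- cis$chrom
      pos1[ic] <- cis$pos1; pos2[ic] <- cis$pos2
    }
  }

  snapped <- snap_to_fragments(fmap, chrom1, pos1, chrom2, pos2)

  res <- tibble(chrom1 = chrom1, pos1 = snapped$pos1,
                strand1 = sample(c("+", "-"), n, replace = TRUE),
                chrom2 = chrom2, pos2 = snapped$pos2,
                strand2 = sample(c("+", "-"), n, replace = TRUE),
                frag1 = snapped$f1, frag2 = snapped$f2,
                mito_fp = FALSE)
  res <- fix_artifact_lookalikes(res, fmap)

  if (config$mito_fp_rate > 0) {
    mito <- genome$chromosomes[genome$chromosomes$class == "mito", ]
    fp <- which(runif(n) < config$mito_fp_rate)
    if (length(fp) > 0) {
      res$chrom2[fp] <- mito$chrom[1]
      res$pos2[fp] <- 1 + floor(runif(length(fp)) * mito$length[1])
      res$mito_fp[fp] <- TRUE
    }
  }
  res$pos1 <- as.integer(round(res$pos1))
  res$pos2 <- as.integer(round(res$pos2))
  select(res, -"frag1", -"frag2")
}

gen_cis_pairs <- function(tb, config, state, phase, boundaries) {
  n <- length(state)
  chrom <- character(n); p1 <- numeric(n); p2 <- numeric(n)
  todo <- seq_len(n)
  max_rounds <- 8L
  for (round in seq_len(max_rounds)) {
    if (length(todo) == 0) break
    m <- length(todo)
    ci <- sample.int(nrow(tb), m, replace = TRUE, prob = tb$weight)
    L <- tb$length[ci]
    smin <- config$min_distance
    s <- draw_cis_distance(m, config$decay_exponent, smin,
                           pmax(smin * 1.01, L - 2))
    s <- s * 2^(config$decay_shift * (phase[todo] - 0.5))
    s <- pmin(pmax(s, smin), L - 2)

    target_early <- runif(m) < p_early_of(phase[todo], config$phase_effect)
    maxa <- pmax(1, L - s - 1)
    anchor <- 1 + floor(runif(m) * maxa)
    for (k in 1:2) {  # two retries toward the preferred repli class
      is_early <- repli_class_of(anchor, config$repli_block_size) == "early"
      miss <- which(is_early != target_early)
      if (length(miss) == 0) break
      anchor[miss] <- 1 + floor(runif(length(miss)) * maxa[miss])
    }
    q1 <- anchor
    q2 <- anchor + round(s)

    if (round == max_rounds) {
      keep <- rep(TRUE, m)
    } else {
      same_tad <- rep(TRUE, m)
      key <- paste(state[todo], tb$chrom[ci])
      for (kk in unique(key)) {
        jj <- which(key == kk)
        st <- state[todo][jj[1]]
        b <- boundaries[[st]][[tb$chrom[ci[jj[1]]]]]
        if (length(b) > 0) {
          same_tad[jj] <- findInterval(q1[jj], b) == findInterval(q2[jj], b)
        }
      }
      keep <- same_tad | runif(m) < 1 / config$tad_weight
      applies <- (q2 - q1) > config$compartment_min_dist
      same_comp <- compartment_parity(q1, config$compartment_block_size) ==
        compartment_parity(q2, config$compartment_block_size)
      keep <- keep & (!applies | same_comp | runif(m) < 1 / config$compartment_weight)
    }

    acc <- which(keep)
    chrom[todo[acc]] <- tb$chrom[ci[acc]]
    p1[todo[acc]] <- q1[acc]
    p2[todo[acc]] <- pmin(q2[acc], L[acc] - 1)
    todo <- todo[!keep]
  }
  list(chrom = chrom, pos1 = p1, pos2 = p2)
}

# Move each end 0-300 bp inside its covering restriction fragment.
snap_to_fragments <- function(fmap, chrom1, pos1, chrom2, pos2) {
  frags <- fmap$fragments
  f1 <- lookup_fragment(fmap, chrom1, pmax(1, round(pos1)))
  f2 <- lookup_fragment(fmap, chrom2, pmax(1, round(pos2)))
  n <- length(f1)
  snap <- function(f) {
    len <- frags$end[f] - frags$start[f]
    frags$start[f] + 1 + floor(runif(length(f)) * pmin(300, len))
  }
  list(pos1 = snap(f1), pos2 = snap(f2), f1 = f1, f2 = f2)
}

# Planted-valid pairs must not look like digestion artifacts: push
# same-fragment cis pairs into a neighbouring fragment and strip the
# inward-strand configuration from adjacent-fragment pairs.
fix_artifact_lookalikes <- function(res, fmap) {
  frags <- fmap$fragments
  cis <- res$chrom1 == res$chrom2
  samef <- which(cis & res$frag1 == res$frag2)
  if (length(samef) > 0) {
    f2 <- res$frag2[samef]
    nxt <- ifelse(f2 < nrow(frags) & frags$chrom[pmin(f2 + 1, nrow(frags))] == res$chrom2[samef],
                  f2 + 1, f2 - 1)
    len <- frags$end[nxt] - frags$start[nxt]
    res$pos2[samef] <- frags$start[nxt] + 1 + floor(runif(length(nxt)) * pmin(300, len))
    res$frag2[samef] <- nxt
  }
  # adjacent fragments with inward strands would classify as religation
  lo_first <- res$pos1 <= res$pos2
  s_lo <- ifelse(lo_first, res$strand1, res$strand2)
  s_hi <- ifelse(lo_first, res$strand2, res$strand1)
  adj <- which(cis & abs(res$frag1 - res$frag2) == 1 & s_lo == "+" & s_hi == "-")
  if (length(adj) > 0) {
    hi_is_2 <- lo_first[adj]
    res$strand2[adj[hi_is_2]] <- "+"
    res$strand1[adj[!hi_is_2]] <- "+"
  }
  res
}

# Replace a fraction of each barcode's rows with copies of earlier-generated
# rows of the same barcode (PCR duplicates).
apply_duplicates <- function(pairs, rate) {
  n <- nrow(pairs)
  if (rate <= 0 || n == 0) {
    pairs$true_duplicate <- logical(n)
    return(pairs)
  }
  first <- !duplicated(pairs$slot_id)
  dup <- runif(n) < rate & !first
  src <- integer(n)
  for (ii in split(seq_len(n), pairs$slot_id)) {
    d <- ii[dup[ii]]
    if (length(d) == 0) next
    nd <- ii[!dup[ii]]
    src[d] <- nd[sample.int(length(nd), length(d), replace = TRUE)]
  }
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
            "mapq1", "mapq2", "species", "true_category", "true_mito_fp")
  sel <- which(dup)
  pairs[sel, cols] <- pairs[src[sel], cols]
  pairs$true_duplicate <- dup
  pairs
}

#' Add loop-anchored contacts to a pair stream
#'
#' Appends `fraction * nrow(pairs)` extra valid cis pairs whose ends fall
#' within `jitter` bp of the anchors of randomly chosen loops — a planted
#' punctate enrichment used to exercise aggregate peak analysis.
#'
#' @param pairs Pair tibble (simulator output or unique valid pairs).
#' @param loops BEDPE-style tibble (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`).
#' @param fraction Extra pairs as a fraction of the input rows.
#' @param jitter Uniform positional jitter around each anchor midpoint, bp.
#' @param seed Seed.
#' @return `pairs` with the loop-anchored rows appended.
#' @export
plant_loop_contacts <- function(pairs, loops, fraction = 0.02, jitter = 10e3,
                                seed = 1) {
  n_new <- round(fraction * nrow(pairs))
  if (n_new == 0) return(pairs)
  with_seed(seed, {
    li <- sample.int(nrow(loops), n_new, replace = TRUE)
    mid1 <- (loops$start1[li] + loops$end1[li]) / 2
    mid2 <- (loops$start2[li] + loops$end2[li]) / 2
    extra <- tibble(
      read_id = sprintf("loop%06d", seq_len(n_new)),
      cell_id = if ("cell_id" %in% names(pairs)) {
        sample(unique(pairs$cell_id), n_new, replace = TRUE)
      } else "bulk",
      chrom1 = loops$chrom1[li],
      pos1 = as.integer(pmax(1, round(mid1 + runif(n_new, -jitter, jitter)))),
      strand1 = sample(c("+", "-"), n_new, replace = TRUE),
      chrom2 = loops$chrom2[li],
      pos2 = as.integer(pmax(1, round(mid2 + runif(n_new, -jitter, jitter)))),
      strand2 = sample(c("+", "-"), n_new, replace = TRUE),
      mapq1 = 60L, mapq2 = 60L,
      true_category = "valid", true_duplicate = FALSE, true_mito_fp = FALSE
    )
    bind_rows(pairs, extra[, intersect(names(extra), names(pairs))])
  })
}

summarise_truth <- function(pairs, profiles, slots) {
  prim <- profiles |>
    filter(.data$role != "secondary") |>
    select("slot_id", "state", "ploidy", "phase")
  mix <- profiles |>
    group_by(.data$slot_id) |>
    summarise(species = paste(sort(unique(.data$species)), collapse = "+"),
              target_pairs = sum(.data$target))
  counts <- pairs |>
    group_by(.data$slot_id) |>
    summarise(
      n_pairs = dplyr::n(),
      n_valid = sum(.data$true_category == "valid"),
      n_dangling_end = sum(.data$true_category == "dangling_end"),
      n_self_circle = sum(.data$true_category == "self_circle"),
      n_religation = sum(.data$true_category == "religation"),
      n_dumped = sum(.data$true_category == "dumped"),
      n_duplicate = sum(.data$true_duplicate),
      n_mito_fp = sum(.data$true_mito_fp)
    )
  slots |>
    left_join(mix, by = "slot_id") |>
    left_join(prim, by = "slot_id") |>
    left_join(counts, by = "slot_id") |>
    mutate(dplyr::across(dplyr::starts_with("n_"), ~ tidyr::replace_na(.x, 0L))) |>
    select(-"slot_id")
}
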