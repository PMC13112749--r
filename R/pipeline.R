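# End-to-end orchestration: simulate -> classify -> call cells -> matrices
# -> tracks -> melting -> phasing, from a single validated configuration.

default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = "schickit_run",
    genome = list(species = c("alpha", "beta"), mean_fragment_spacing = 500),
    simulate = list(n_cells = list(alpha = 40, beta = 40),
                    pairs_per_cell = 2000, doublet_rate = 0.05,
                    n_background_barcodes = 300, duplicate_rate = 0.1,
                    mito_fp_rate = 0.01, trans_rate = 0.1),
    classify = list(min_mapq = 10),
    call_cells = list(enabled = TRUE, sensitivity = 1, species_threshold = 0.89),
    matrices = list(bin_size = "50k", max_iter = 200, tol = 1e-5,
                    mask_percentile = 0.02),
    tracks = list(enabled = TRUE, min_depth = "200k", max_depth = "750k",
                  step = "50k", delta = 0.01),
    melting = list(enabled = TRUE, chrom = "chrA1", start = 12e6, end = 15e6,
                   depth_guard = "250k"),
    phasing = list(enabled = TRUE)
  )
}

unit_fields <- c("pairs_per_cell", "bin_size", "min_depth", "max_depth",
                 "step", "depth_guard", "start", "end")

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Unknown keys are rejected with
#' the nearest valid key named; missing keys are filled with defaults;
#' numeric fields accept `k`/`M` suffixes ("200k" becomes 200000). The
#' resolved configuration re-validates to itself, and [run_pipeline()]
#' echoes it next to its outputs.
#'
#' @param config Path to a YAML file or a nested list.
#' @return A normalized `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("configuration must be a YAML file or a list")
  defaults <- default_pipeline_config()

  errors <- character(0)
  check_keys <- function(given, known, where) {
    for (k in setdiff(names(given), known)) {
      near <- agrep(k, known, max.distance = 2, value = TRUE)
      hint <- if (length(near) > 0) sprintf(" (did you mean '%s'?)", near[1]) else ""
      errors <<- c(errors, sprintf("unknown key '%s' in %s%s", k, where, hint))
    }
  }
  check_keys(config, names(defaults), "top level")
  out <- defaults
  for (sec in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sec]])) {
      if (!is.list(config[[sec]])) {
        errors <- c(errors, sprintf("section '%s' must be a mapping", sec))
        next
      }
      check_keys(config[[sec]], names(defaults[[sec]]), sprintf("section '%s'", sec))
      for (k in intersect(names(config[[sec]]), names(defaults[[sec]]))) {
        out[[sec]][[k]] <- config[[sec]][[k]]
      }
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  if (length(errors) > 0) {
    abort(paste(c("invalid pipeline configuration:", errors), collapse = "\n  "))
  }
  # expand unit suffixes on numeric fields
  for (sec in names(out)) {
    if (!is.list(out[[sec]])) next
    for (k in intersect(names(out[[sec]]), unit_fields)) {
      out[[sec]][[k]] <- expand_units(out[[sec]][[k]])
    }
  }
  out$seed <- as.integer(expand_units(out$seed))
  structure(out, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulation, classification and
#' QC, knee cell calling (plus species assignment and collision rate with
#' two species), pseudo-bulk matrices with iterative correction and decay,
#' insulation/compartment tracks, melting-state detection and cell phasing —
#' writing tabular artifacts into `config$outdir` together with the resolved
#' configuration and a YAML run report. Per-stage seeds are derived from the
#' global seed, so re-running an identical configuration reproduces
#' byte-identical tabular outputs, and disabling a downstream stage never
#' perturbs upstream results.
#'
#' @param config A [validate_config()] result, a list, or a YAML path.
#' @return A `run_report` list (stage records, per-cell QC roll-up), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$outdir, "config_resolved.yaml"))
  report <- list(stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(list(...), elapsed_s = round(unname(
      proc.time()["elapsed"] - t0), 2))
  }

  ## simulate ---------------------------------------------------------------
  t0 <- proc.time()["elapsed"]
  genomes <- lapply(config$genome$species, function(sp) {
    toy_genome(sp, mean_fragment_spacing = config$genome$mean_fragment_spacing,
               seed = derive_seed(config$seed, paste0("genome_", sp)))
  })
  names(genomes) <- config$genome$species
  simc <- config$simulate
  cfg <- sim_config(n_cells = unlist(simc$n_cells),
                    pairs_per_cell = simc$pairs_per_cell,
                    doublet_rate = simc$doublet_rate,
                    n_background_barcodes = simc$n_background_barcodes,
                    duplicate_rate = simc$duplicate_rate,
                    mito_fp_rate = simc$mito_fp_rate,
                    trans_rate = simc$trans_rate,
                    seed = derive_seed(config$seed, "simulate"))
  sim <- simulate_cells(genomes, cfg)
  readr::write_tsv(sim$barcodes, file.path(config$outdir, "ground_truth.tsv"))
  note("simulate", n_pairs = nrow(sim$pairs), n_barcodes = nrow(sim$barcodes))

  ## classify + QC ----------------------------------------------------------
  t0 <- proc.time()["elapsed"]
  fmap <- digest_genome(genomes)
  cls <- classify_pairs(sim$pairs, fmap, min_mapq = config$classify$min_mapq) |>
    deduplicate()
  qc <- cell_qc(cls, genomes)
  readr::write_tsv(qc, file.path(config$outdir, "cell_qc.tsv"))
  note("classify", n_pairs = nrow(cls), n_cells = nrow(qc),
       min_mapq = config$classify$min_mapq)

  valid_cells <- qc$cell_id
  species_calls <- NULL
  if (isTRUE(config$call_cells$enabled)) {
    t0 <- proc.time()["elapsed"]
    curve <- rank_barcodes(qc)
    knees <- find_knees(curve, sensitivity = config$call_cells$sensitivity)
    readr::write_tsv(tidy(knees), file.path(config$outdir, "rank_curve.tsv"))
    valid_cells <- knees$barcodes$cell_id[knees$barcodes$label == "valid"]
    coll <- NULL
    if (length(genomes) == 2 && length(valid_cells) > 0) {
      sc <- species_pair_counts(filter(cls, .data$cell_id %in% valid_cells), genomes)
      species_calls <- assign_species(sc, threshold = config$call_cells$species_threshold)
      coll <- collision_rate(species_calls)
      readr::write_tsv(species_calls, file.path(config$outdir, "species_calls.tsv"))
      readr::write_tsv(coll, file.path(config$outdir, "collision_rate.tsv"))
    }
    note("call_cells", knee1 = knees$knee1, knee2 = knees$knee2,
         n_valid = length(valid_cells),
         collision_rate = if (!is.null(coll)) coll$rate else NA)
  }

  if (length(valid_cells) == 0) {
    warn("cell calling retained no barcodes; downstream stages use all barcodes")
    valid_cells <- qc$cell_id
  }
  uval <- filter(cls, .data$category == "valid", !.data$duplicate,
                 .data$cell_id %in% valid_cells)
  g1 <- genomes[[1]]
  uval1 <- filter(uval, .data$chrom1 %in% g1$chromosomes$chrom,
                  .data$chrom2 %in% g1$chromosomes$chrom)

  ## pseudo-bulk matrices ---------------------------------------------------
  t0 <- proc.time()["elapsed"]
  mat <- bin_contacts(uval1, g1, bin_size = config$matrices$bin_size)
  mat <- ice_balance(mat, max_iter = config$matrices$max_iter,
                     tol = config$matrices$tol,
                     mask_percentile = config$matrices$mask_percentile)
  decay <- distance_decay(uval1)
  readr::write_tsv(decay, file.path(config$outdir, "distance_decay.tsv"))
  readr::write_tsv(contact_counts(mat), file.path(config$outdir, "matrix_coo.tsv"))
  note("matrices", n_unique_valid = nrow(uval1), bin_size = config$matrices$bin_size,
       ice_converged = mat$converged)

  insul <- NULL
  if (isTRUE(config$tracks$enabled)) {
    t0 <- proc.time()["elapsed"]
    insul <- insulation_scores(mat, min_depth = config$tracks$min_depth,
                               max_depth = config$tracks$max_depth,
                               step = config$tracks$step)
    bnd <- call_boundaries(insul, delta = config$tracks$delta)
    eig <- compartment_eigenvector(mat, sim_compartment_track(g1, cfg,
                                                              config$matrices$bin_size))
    write_bedgraph(insul, file.path(config$outdir, "insulation.bedgraph"),
                   value_col = "score")
    write_bed(bnd, file.path(config$outdir, "boundaries.bed"))
    write_bedgraph(eig, file.path(config$outdir, "compartments.bedgraph"),
                   value_col = "eigen")
    note("tracks", n_boundaries = nrow(bnd),
         n_eigen_bins = sum(!is.na(eig$eigen)))
  }

  if (isTRUE(config$melting$enabled)) {
    t0 <- proc.time()["elapsed"]
    roi <- config$melting
    sc_cells <- insulation_by_cell(uval1, g1, roi$chrom,
                                   bin_size = config$matrices$bin_size,
                                   min_depth = config$tracks$min_depth,
                                   max_depth = config$tracks$max_depth,
                                   step = config$tracks$step) |>
      filter(.data$start >= roi$start, .data$end <= roi$end, .data$valid)
    guard <- depth_guard(qc[qc$cell_id %in% valid_cells,
                            c("cell_id", "unique_valid_pairs")],
                         threshold = roi$depth_guard)
    ok <- dplyr::n_distinct(sc_cells$cell_id) >= 4
    if (ok) {
      clust <- cluster_states(sc_cells)
      ms <- melting_score(sc_cells, clust)
      readr::write_tsv(tidy(clust), file.path(config$outdir, "melting_states.tsv"))
      readr::write_tsv(ms, file.path(config$outdir, "melting_score.tsv"))
      note("melting", n_cells = nrow(clust$cells), D = ms$D, p_value = ms$p_value,
           n_low_depth = guard$n_low, stable = clust$stable)
    } else {
      note("melting", skipped = "fewer than 4 cells with ROI scores",
           n_low_depth = guard$n_low)
    }
  }

  if (isTRUE(config$phasing$enabled)) {
    t0 <- proc.time()["elapsed"]
    rs <- repli_score(uval1, sim_repli_domains(g1, cfg))
    phasing <- rs
    has_sex <- all(c("sex_X", "sex_Y") %in% g1$chromosomes$class)
    if (has_sex) {
      hs <- haploid_score(uval1, g1)
      phasing <- left_join(rs, hs, by = "cell_id")
    }
    readr::write_tsv(phasing, file.path(config$outdir, "phasing.tsv"))
    note("phasing", n_cells = nrow(rs), haploid_score = has_sex)
  }

  report$qc_summary <- list(
    n_valid_cells = length(valid_cells),
    mean_valid_pair_ratio = round(mean(qc$valid_pair_ratio, na.rm = TRUE), 4),
    mean_reported_pair_ratio = round(mean(qc$reported_pair_ratio, na.rm = TRUE), 4),
    mean_dup_rate = round(mean(qc$dup_rate, na.rm = TRUE), 4),
    median_log2_cis_trans = round(median(qc$log2_cis_trans, na.rm = TRUE), 4)
  )
  yaml::write_yaml(report, file.path(config$outdir, "run_report.yaml"))
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (st in names(x$stages)) {
    rec <- x$stages[[st]]
    cat(sprintf("  %-10s %s\n", st,
                paste(names(rec), vapply(rec, function(v) paste(format(v), collapse = ","),
                                         character(1)), sep = "=", collapse = " ")))
  }
  invisible(x)
}
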