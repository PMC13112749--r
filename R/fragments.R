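#' Digest a genome into a restriction-fragment map
#'
#' Builds the fragment map used for contact-pair classification. For a
#' `toy_genome` the stored cut-site map is used directly. For a FASTA file
#' (or a `Biostrings::DNAStringSet`) all forward-strand occurrences of the
#' motif are located (`GATC` is its own reverse complement, so a forward scan
#' is exhaustive) and the cut is placed at occurrence start plus `cut_offset`
#' (default 0, the DpnII `^GATC` convention). Fragments are half-open and
#' 0-based internally.
#'
#' @param x A `toy_genome`, a FASTA file path, or a `DNAStringSet`.
#' @param motif Recognition motif (non-empty character scalar).
#' @param cut_offset Offset of the cut within the motif, in `[0, nchar(motif)]`.
#' @return A `fragment_map`: list with `fragments` (tibble `chrom`, `start`,
#'   `end`, `frag_id`), `cut_sites` (named list), and `chrom_lengths`.
#' @examples
#' fm <- digest_genome(toy_genome("alpha", seed = 1))
#' head(fm$fragments)
#' @export
digest_genome <- function(x, motif = "GATC", cut_offset = 0) {
  if (!is.character(motif) || nchar(motif) == 0) abort("`motif` must be non-empty")
  if (cut_offset < 0 || cut_offset > nchar(motif)) {
    abort("`cut_offset` must lie within the motif")
  }

  if (inherits(x, "toy_genome") ||
      (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, logical(1), "toy_genome")))) {
    genomes <- as_genome_list(x)
    lens <- unlist(unname(lapply(genomes, function(g) {
      setNames(g$chromosomes$length, g$chromosomes$chrom)
    })))
    cuts <- do.call(c, unname(lapply(genomes, function(g) g$cut_sites)))
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Biostrings is required to digest FASTA input")
    }
    seqs <- if (is.character(x)) {
      if (!file.exists(x)) abort(sprintf("cannot read FASTA file '%s'", x))
      Biostrings::readDNAStringSet(x)
    } else {
      x
    }
    lens <- setNames(Biostrings::width(seqs), names(seqs))
    hits <- Biostrings::vmatchPattern(motif, seqs)
    cuts <- setNames(lapply(seq_along(seqs), function(i) {
      as.integer(sort(Biostrings::start(hits[[i]]) - 1L + cut_offset))
    }), names(seqs))
    # drop a cut at position 0 or chromosome end: it would create an empty fragment
    cuts <- lapply(names(cuts), function(ch) {
      cc <- cuts[[ch]]
      cc[cc > 0 & cc < lens[[ch]]]
    })
    names(cuts) <- names(lens)
  }

  frag_tbl <- purrr::map_dfr(names(lens), function(ch) {
    cc <- cuts[[ch]]
    tibble(chrom = ch,
           start = as.integer(c(0, cc)),
           end = as.integer(c(cc, lens[[ch]])))
  })
  frag_tbl <- mutate(frag_tbl, frag_id = seq_len(nrow(frag_tbl)))

  offsets <- frag_tbl |>
    group_by(.data$chrom) |>
    summarise(first_id = min(.data$frag_id), n_frag = dplyr::n()) |>
    ungroup()

  structure(
    list(fragments = frag_tbl,
         cut_sites = cuts,
         chrom_lengths = lens,
         offsets = setNames(offsets$first_id, offsets$chrom),
         motif = motif),
    class = "fragment_map"
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map> %d chromosomes, %d fragments (motif %s)\n",
              length(x$chrom_lengths), nrow(x$fragments), x$motif))
  invisible(x)
}

#' Locate the restriction fragment covering each position
#'
#' Vectorized binary-search lookup. Positions are 1-based; each position maps
#' to the unique half-open fragment covering it.
#'
#' @param map A `fragment_map`.
#' @param chrom,pos Equal-length vectors of chromosome names and 1-based
#'   positions.
#' @return Integer vector of global fragment ids.
#' @export
lookup_fragment <- function(map, chrom, pos) {
  stopifnot(inherits(map, "fragment_map"), length(chrom) == length(pos))
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(map$chrom_lengths)) {
      abort(sprintf("chromosome '%s' is not covered by the fragment map", ch))
    }
    p <- pos[idx]
    if (any(p < 1 | p > map$chrom_lengths[[ch]])) {
      abort(sprintf("position beyond chromosome length on '%s'", ch))
    }
    local <- findInterval(p - 1, map$cut_sites[[ch]]) + 1L
    out[idx] <- map$offsets[[ch]] + local - 1L
  }
  out
}
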