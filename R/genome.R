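#' Build a toy genome with a restriction-site map
#'
#' Constructs a small multi-chromosome genome for one species together with a
#' map of restriction cut sites, emulating a DpnII (`GATC`) digest. Cut sites
#' are drawn as a homogeneous point process with exponential inter-arrival
#' distances (mean `mean_fragment_spacing`), which matches the spacing
#' statistics of a 4-bp cutter without requiring an actual sequence scan.
#' The realized site map is deterministic under `seed`.
#'
#' Two built-in species are provided: `"alpha"` (two autosomes, an X, a Y and
#' a mitochondrial chromosome) and `"beta"` (two autosomes plus mitochondrial),
#' sized so that 50-kb binning is meaningful at desk scale. Chromosome names
#' are unique across the two species so that barnyard (species-mixing)
#' experiments can run on the combined genome.
#'
#' @param species Species tag: `"alpha"`, `"beta"`, or any label when
#'   `chromosomes` is supplied.
#' @param chromosomes Optional tibble with columns `chrom`, `length`, `class`
#'   (one of `autosome`, `sex_X`, `sex_Y`, `mito`). Exactly one `mito`
#'   chromosome is required.
#' @param mean_fragment_spacing Mean restriction-fragment length in bp.
#' @param seed Integer seed controlling the cut-site draw.
#' @return An object of class `toy_genome`: a list with `species`,
#'   `chromosomes` (tibble) and `cut_sites` (named list of sorted 0-based cut
#'   positions per chromosome).
#' @examples
#' gn <- toy_genome("alpha", seed = 1)
#' genome_fragments(gn)
#' @export
toy_genome <- function(species = c("alpha", "beta"), chromosomes = NULL,
                       mean_fragment_spacing = 500, seed = 1) {
  if (is.null(chromosomes)) {
    species <- match.arg(species)
    chromosomes <- default_chromosomes(species)
  } else {
    species <- species[[1]]
    chromosomes <- as_tibble(chromosomes)
  }
  assert_columns(chromosomes, c("chrom", "length", "class"), "chromosome spec")
  if (!is_scalar_number(mean_fragment_spacing) || mean_fragment_spacing <= 0) {
    abort("`mean_fragment_spacing` must be a positive number")
  }
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be positive")
  if (sum(chromosomes$class == "mito") != 1L) {
    abort("exactly one mitochondrial chromosome is required per species")
  }
  bad <- setdiff(unique(chromosomes$class), c("autosome", "sex_X", "sex_Y", "mito"))
  if (length(bad) > 0) abort(sprintf("unknown chromosome class: %s", bad[1]))
  if (any(chromosomes$length < 10 * mean_fragment_spacing & chromosomes$class != "mito")) {
    warn("some chromosomes are shorter than 10x the mean fragment spacing")
  }

  cut_sites <- with_seed(seed, {
    setNames(lapply(seq_len(nrow(chromosomes)), function(i) {
      draw_cut_sites(chromosomes$length[i], mean_fragment_spacing)
    }), chromosomes$chrom)
  })

  structure(
    list(species = species,
         chromosomes = chromosomes,
         cut_sites = cut_sites,
         mean_fragment_spacing = mean_fragment_spacing,
         seed = as.integer(seed)),
    class = "toy_genome"
  )
}

default_chromosomes <- function(species) {
  switch(species,
    alpha = tibble(
      chrom  = c("chrA1", "chrA2", "chrX", "chrY", "chrM"),
      length = c(20e6, 15e6, 5e6, 1e6, 16e3),
      class  = c("autosome", "autosome", "sex_X", "sex_Y", "mito")
    ),
    beta = tibble(
      chrom  = c("chrB1", "chrB2", "chrBM"),
      length = c(18e6, 12e6, 16e3),
      class  = c("autosome", "autosome", "mito")
    ),
    abort(sprintf("no built-in chromosome table for species '%s'", species))
  )
}

# Exponential inter-arrival cut positions on [1, len); 0-based, sorted,
# spaced >= 4 bp apart so a 4-bp motif can be planted at each site.
draw_cut_sites <- function(len, spacing) {
  n_expect <- ceiling(len / spacing * 1.5) + 10
  gaps <- rexp(n_expect, rate = 1 / spacing)
  pos <- floor(cumsum(gaps))
  while (length(pos) > 0 && pos[length(pos)] < len - 1) {
    gaps <- rexp(n_expect, rate = 1 / spacing)
    pos <- c(pos, pos[length(pos)] + floor(cumsum(gaps)))
  }
  pos <- pos[pos >= 1 & pos <= len - 5]
  pos <- pos[c(TRUE, diff(pos) >= 4)]
  as.integer(sort(unique(pos)))
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> species '%s': %d chromosomes, %s bp, %d cut sites\n",
              x$species, nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              sum(lengths(x$cut_sites))))
  invisible(x)
}

#' Chromosome size table of one or more toy genomes
#'
#' @param genome A `toy_genome` or a list of them.
#' @return Tibble with `chrom`, `length`, `class`, `species`.
#' @export
chrom_sizes <- function(genome) {
  genomes <- as_genome_list(genome)
  purrr::map_dfr(genomes, function(g) {
    mutate(g$chromosomes, species = g$species)
  })
}

as_genome_list <- function(genome) {
  if (inherits(genome, "toy_genome")) return(list(genome))
  if (is.list(genome) && all(vapply(genome, inherits, logical(1), "toy_genome"))) {
    return(genome)
  }
  abort("expected a `toy_genome` or a list of `toy_genome` objects")
}

#' Restriction-fragment intervals of a toy genome
#'
#' Fragments are half-open, 0-based intervals that tile each chromosome
#' exactly; the fragment count per chromosome is the cut-site count plus one.
#'
#' @param genome A `toy_genome` or list of them.
#' @return Tibble with `chrom`, `start`, `end`, `frag_id` (global index).
#' @export
genome_fragments <- function(genome) {
  genomes <- as_genome_list(genome)
  frags <- purrr::map_dfr(genomes, function(g) {
    purrr::map_dfr(g$chromosomes$chrom, function(ch) {
      len <- g$chromosomes$length[g$chromosomes$chrom == ch]
      cuts <- g$cut_sites[[ch]]
      starts <- c(0, cuts)
      ends <- c(cuts, len)
      tibble(chrom = ch, start = as.integer(starts), end = as.integer(ends))
    })
  })
  mutate(frags, frag_id = seq_len(nrow(frags)))
}

#' Write a toy genome as FASTA with planted restriction motifs
#'
#' Emits one record per chromosome. The background sequence is drawn from
#' the alphabet `{A, C, T}` only, so the recognition motif cannot occur by
#' chance; the literal motif (default `GATC`) is planted at every cut site.
#' Re-digesting the emitted FASTA therefore reproduces the genome's cut-site
#' map exactly.
#'
#' @param genome A `toy_genome`.
#' @param path Output FASTA path.
#' @param motif Motif planted at each cut site.
#' @param seed Seed for the background sequence.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, motif = "GATC", seed = 1) {
  stopifnot(inherits(genome, "toy_genome"))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to write FASTA")
  }
  mlen <- nchar(motif)
  seqs <- with_seed(seed, {
    lapply(genome$chromosomes$chrom, function(ch) {
      len <- genome$chromosomes$length[genome$chromosomes$chrom == ch]
      base <- sample(c("A", "C", "T"), len, replace = TRUE)
      for (cut in genome$cut_sites[[ch]]) {
        base[(cut + 1):(cut + mlen)] <- strsplit(motif, "")[[1]]
      }
      paste(base, collapse = "")
    })
  })
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- genome$chromosomes$chrom
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}
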