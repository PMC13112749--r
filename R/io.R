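# Readers/writers for the plain-text interchange formats: the pairs dialect
# (4DN-pairs-like with cell and category columns), BED, bedGraph, BEDPE and
# whitelist TSVs.

PAIRS_COLUMNS <- c("readID", "chrom1", "pos1", "chrom2", "pos2",
                   "strand1", "strand2", "cellID", "category", "duplicate")

#' Write contact pairs in the package's pairs dialect
#'
#' Tab-separated with `#`-prefixed header lines, columns `readID chrom1 pos1
#' chrom2 pos2 strand1 strand2 cellID category duplicate`; positions are
#' 1-based. Missing `category`/`duplicate` columns are written as `.` / 0.
#'
#' @param pairs Pairs tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  assert_columns(pairs, c("chrom1", "pos1", "chrom2", "pos2",
                          "strand1", "strand2"), "pair stream")
  out <- tibble(
    readID = pairs$read_id %||% sprintf("r%08d", seq_len(nrow(pairs))),
    chrom1 = pairs$chrom1, pos1 = pairs$pos1,
    chrom2 = pairs$chrom2, pos2 = pairs$pos2,
    strand1 = pairs$strand1, strand2 = pairs$strand2,
    cellID = pairs$cell_id %||% ".",
    category = pairs$category %||% ".",
    duplicate = as.integer(pairs$duplicate %||% FALSE)
  )
  writeLines(c("## pairs format v1.0-schickit",
               paste0("#columns: ", paste(PAIRS_COLUMNS, collapse = " "))),
             path)
  readr::write_tsv(out, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Read the package's pairs dialect
#'
#' @param path Pairs file written by [write_pairs()].
#' @return Tibble with `read_id`, `cell_id`, coordinate/strand columns and,
#'   when present, `category` and `duplicate`.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = PAIRS_COLUMNS,
                        col_types = "ccicicccci", progress = FALSE)
  tibble(read_id = df$readID,
         cell_id = df$cellID,
         chrom1 = df$chrom1, pos1 = df$pos1, strand1 = df$strand1,
         chrom2 = df$chrom2, pos2 = df$pos2, strand2 = df$strand2,
         category = df$category,
         duplicate = df$duplicate == 1L)
}

#' Write genomic intervals as BED (0-based, half-open)
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally a name
#'   column.
#' @param path Output path.
#' @param name_col Optional column written as the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  assert_columns(intervals, c("chrom", "start", "end"), "interval table")
  out <- select(intervals, "chrom", "start", "end")
  if (!is.null(name_col)) out$name <- intervals[[name_col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value_col Value column (default: the first non-coordinate column).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = NULL) {
  assert_columns(track, c("chrom", "start", "end"), "track")
  vc <- value_col %||%
    setdiff(names(track), c("chrom", "start", "end", "bin_id", "valid"))[1]
  out <- track |>
    filter(!is.na(.data[[vc]])) |>
    select("chrom", "start", "end", dplyr::all_of(vc))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path.
#' @param value_name Name for the value column.
#' @return Tibble `chrom`, `start`, `end`, value.
#' @export
read_bedgraph <- function(path, value_name = "score") {
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("chrom", "start", "end", value_name),
                        col_types = "ciid", progress = FALSE)
  as_tibble(df)
}

#' Read a BEDPE loop list
#'
#' @param path BEDPE path (first six columns used).
#' @return Tibble `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`.
#' @export
read_bedpe <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE)
  if (ncol(df) < 6) abort("BEDPE needs at least 6 columns")
  out <- df[, 1:6]
  names(out) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  as_tibble(out)
}

#' Write / read a barcode whitelist (index TAB sequence)
#'
#' @param codes Character vector of codes.
#' @param path TSV path.
#' @return `path` invisibly (write); character vector (read).
#' @export
write_whitelist <- function(codes, path) {
  readr::write_tsv(tibble(index = seq_along(codes), sequence = codes),
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  df <- readr::read_tsv(path, col_names = c("index", "sequence"),
                        col_types = "ic", progress = FALSE)
  df$sequence[order(df$index)]
}
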