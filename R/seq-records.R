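#' 5'UTR variant libraries
#'
#' A `utr_library` is a tibble with one row per 5'UTR variant and columns
#' `id`, `sequence` (DNA alphabet, `U` mapped to `T` on input), `architecture`
#' (one of `"fixed_end_50"`, `"random_end_25"`, `"random_end_50"`), `prefix`
#' (the constant 5' region preceding the variable segment, including the
#' `GGG` appended by in vitro transcription) and `cds_offset` (0-based
#' transcript position of the `A` of the main-ORF AUG, which immediately
#' follows the UTR). Coordinates throughout the package are 0-based from the
#' transcript 5' end (the first IVT `G`), with half-open intervals.
#'
#' @param id Character vector of unique variant labels.
#' @param sequence Character vector of variable-region sequences over
#'   `{A,C,G,T,U}`; `U` is converted to `T`.
#' @param architecture Library architecture, recycled to the table length.
#' @param prefix Constant 5' prefix. Defaults to `"GGG"` for random-end
#'   architectures. The fixed-end constant region is not hard-coded: supply it
#'   explicitly (it is configuration, defaulting to `GGG` plus a documented
#'   22-nt stand-in ending in `A`, as implied by the library design).
#' @return A `utr_library` tibble.
#' @examples
#' lib <- utr_library(c("u1", "u2"), c("ACGTACGTACGTACGTACGTACGTA", "TTTTTCCCCCTTTTTCCCCCTTTTT"),
#'                    architecture = "random_end_25")
#' lib$cds_offset  # prefix (GGG) + 25
#' @export
utr_library <- function(id, sequence,
                        architecture = c("random_end_25", "random_end_50",
                                         "fixed_end_50"),
                        prefix = NULL) {
  architecture <- match.arg(architecture)
  if (anyDuplicated(id)) abort("variant ids must be unique")
  sequence <- normalize_dna(sequence)
  expected_len <- arch_length(architecture)
  bad <- which(nchar(sequence) != expected_len)
  if (length(bad)) {
    abort(sprintf("sequence %s has length %d; architecture '%s' requires %d",
                  id[bad[1]], nchar(sequence[bad[1]]), architecture,
                  expected_len))
  }
  if (is.null(prefix)) {
    prefix <- if (architecture == "fixed_end_50") fixed_end_default_prefix()
              else "GGG"
  }
  prefix <- normalize_dna(prefix)
  if (architecture != "fixed_end_50" && !identical(prefix, "GGG")) {
    abort("random-end architectures have prefix exactly 'GGG'")
  }
  out <- tibble(id = as.character(id), sequence = sequence,
                architecture = architecture, prefix = prefix,
                cds_offset = nchar(prefix) + nchar(sequence))
  class(out) <- c("utr_library", class(out))
  out
}

#' @rdname utr_library
#' @details `fixed_end_default_prefix()` returns the default constant 5'
#'   region used for fixed-end libraries: the IVT `GGG` followed by a 22-nt
#'   synthetic stand-in ending in `A`. The true constant region of any given
#'   fixed-end library should be supplied via `prefix=`; only its terminal `A`
#'   matters to the analyses in this package (it can complete an `ATG` with a
#'   variable region starting `TG`).
#' @export
fixed_end_default_prefix <- function() {
  paste0("GGG", "ACATTTGCTTCTGACACAACTA")
}

arch_length <- function(architecture) {
  switch(architecture,
         fixed_end_50 = 50L, random_end_25 = 25L, random_end_50 = 50L,
         abort(sprintf("unknown architecture '%s'", architecture)))
}

#' Normalize nucleotide strings to the internal DNA alphabet
#'
#' Uppercases, maps `U` to `T`, and validates that only `{A,C,G,T}` remain.
#'
#' @param x Character vector of sequences.
#' @return Character vector over `{A,C,G,T}`.
#' @export
normalize_dna <- function(x) {
  x <- chartr("u", "t", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grep("[^ACGT]", x)
  if (length(bad)) {
    abort(sprintf("non-ACGT character in sequence at entry %d: '%s'",
                  bad[1], x[bad[1]]))
  }
  x
}

#' Full transcript sequences of a library
#'
#' Concatenates the constant prefix and the variable region; the main-ORF AUG
#' begins at `cds_offset` (immediately after).
#'
#' @param lib A `utr_library`.
#' @return Character vector of transcript 5' ends (prefix + variable region).
#' @export
transcript_sequence <- function(lib) {
  paste0(lib$prefix, lib$sequence)
}

#' Read and write 5'UTR libraries as FASTA or TSV
#'
#' `read_utr_fasta()` reads a FASTA file of variable-region sequences;
#' `write_utr_fasta()` writes one. `read_utr_tsv()` reads a tab-separated
#' table with columns `id`, `sequence` and optionally `architecture`.
#' Alphabet violations are reported with the offending record.
#'
#' @param path File path.
#' @param architecture Architecture assigned to all records.
#' @param prefix Optional constant prefix (see [utr_library()]).
#' @param lib A `utr_library` to write.
#' @return A `utr_library` (readers) or `path`, invisibly (writer).
#' @export
read_utr_fasta <- function(path, architecture = "random_end_25",
                           prefix = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  utr_library(names(seqs), as.character(seqs), architecture = architecture,
              prefix = prefix)
}

#' @rdname read_utr_fasta
#' @export
write_utr_fasta <- function(lib, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    setNames(lib$sequence, lib$id)), path)
  invisible(path)
}

#' @rdname read_utr_fasta
#' @export
read_utr_tsv <- function(path, architecture = "random_end_25", prefix = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(df))) {
    abort(sprintf("%s: expected columns 'id' and 'sequence'", path))
  }
  if ("architecture" %in% names(df)) {
    archs <- unique(df$architecture)
    if (length(archs) != 1L) abort("mixed architectures in one table")
    architecture <- archs
  }
  for (i in seq_len(nrow(df))) {
    if (grepl("[^ACGTUacgtu]", df$sequence[i])) {
      abort(sprintf("%s line %d: non-nucleotide character in '%s'",
                    path, i + 1L, df$id[i]))
    }
  }
  utr_library(df$id, df$sequence, architecture = architecture, prefix = prefix)
}
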