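#' Scan a transcript for upstream start codons
#'
#' Finds every occurrence of a codon from `codon_set` that lies entirely
#' upstream of the main-ORF AUG (`p + 3 <= cds_offset`), over the constant
#' prefix plus variable region. Each hit is classified as in-frame or
#' out-of-frame relative to the main ORF: in-frame iff
#' `(cds_offset - position) %% 3 == 0`.
#'
#' @param record One row of a `utr_library`, or a list/tibble with
#'   `sequence`, `prefix`, `cds_offset`; alternatively a plain transcript
#'   string together with `cds_offset`.
#' @param codon_set Character vector of 3-mers to scan for (default `ATG`).
#' @param cds_offset Required when `record` is a plain string.
#' @return A tibble with columns `position` (0-based from transcript start),
#'   `codon`, and `frame` (`"in_frame"` / `"out_of_frame"`), sorted by
#'   position. Zero rows when there is no hit.
#' @examples
#' scan_start_codons("GGGATGGCCATG", cds_offset = 9)
#' @export
scan_start_codons <- function(record, codon_set = "ATG", cds_offset = NULL) {
  if (length(codon_set) == 0L) abort("codon_set must be non-empty")
  codon_set <- normalize_dna(codon_set)
  if (any(nchar(codon_set) != 3L)) abort("codon_set entries must be 3-mers")
  tr <- as_transcript(record, cds_offset)
  hits <- scan_motifs(tr$transcript, codon_set, max_start = tr$cds_offset - 3L)
  frame <- ifelse((tr$cds_offset - hits$position) %% 3L == 0L,
                  "in_frame", "out_of_frame")
  tibble(position = hits$position, codon = hits$motif, frame = frame)
}

#' Find oligopyrimidine tracts
#'
#' Reports every 0-based transcript position `p` such that all of
#' `transcript[p : p + tract_length]` is a pyrimidine (`C` or `T`);
#' overlapping tracts are all reported.
#'
#' @inheritParams scan_start_codons
#' @param tract_length Tract length in nt (default 5).
#' @return Integer vector of 0-based start positions.
#' @examples
#' find_pyrimidine_tracts("GGGTTTTTAAA", cds_offset = 11)
#' @export
find_pyrimidine_tracts <- function(record, tract_length = 5L,
                                   cds_offset = NULL) {
  if (tract_length < 1L) abort("tract_length must be >= 1")
  tr <- as_transcript(record, cds_offset)
  chars <- strsplit(tr$transcript, "")[[1]]
  pyr <- chars %in% c("C", "T")
  n <- length(pyr)
  if (n < tract_length) return(integer(0))
  ok <- rep(TRUE, n - tract_length + 1L)
  for (j in seq_len(tract_length)) {
    ok <- ok & pyr[seq.int(j, n - tract_length + j)]
  }
  which(ok) - 1L
}

# Accepts a utr_library row, list, or plain string; returns transcript string
# plus cds_offset (defaults to full transcript length for plain strings).
as_transcript <- function(record, cds_offset = NULL) {
  if (is.character(record) && length(record) == 1L) {
    transcript <- normalize_dna(record)
    if (is.null(cds_offset)) cds_offset <- nchar(transcript)
  } else {
    if (is_tibble(record)) {
      stopifnot(nrow(record) == 1L)
      record <- as.list(record)
    }
    transcript <- paste0(record$prefix, record$sequence)
    cds_offset <- record$cds_offset
  }
  if (cds_offset < 0L || cds_offset > nchar(transcript)) {
    abort("cds_offset outside transcript")
  }
  list(transcript = transcript, cds_offset = cds_offset)
}

# Vectorized fixed-width motif scan; returns 0-based positions <= max_start.
scan_motifs <- function(transcript, motifs, max_start) {
  w <- nchar(motifs[1])
  n <- nchar(transcript)
  last <- min(max_start, n - w)
  if (last < 0L) {
    return(list(position = integer(0), motif = character(0)))
  }
  starts <- 0:last
  words <- substring(transcript, starts + 1L, starts + w)
  keep <- words %in% motifs
  list(position = starts[keep], motif = words[keep])
}
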