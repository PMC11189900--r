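#' Quality- and adapter-filter raw MPRA reads
#'
#' Retains reads whose mean base quality exceeds `q_min` and (for random-end
#' libraries prepared by template switching) whose observed bases adjacent to
#' the template-switch junction match the expected template-switching oligo
#' within `max_edit` Levenshtein edits. Set `ts_oligo = NULL` to skip the
#' template-switch check (fixed-end libraries).
#'
#' @param reads A tibble of read records with columns `variant_id` (or
#'   `variable_region`), `umi`, `mean_q`, `fraction_id` and, when TS matching
#'   is requested, `ts_suffix`.
#' @param ts_oligo Expected template-switching oligo sequence, or `NULL`.
#' @param q_min Mean quality threshold; reads with `mean_q > q_min` are kept.
#' @param max_edit Maximum edit distance between `ts_suffix` and `ts_oligo`.
#' @return The retained reads, with a `"filter_log"` attribute counting drops
#'   by reason (`low_quality`, `ts_mismatch`).
#' @export
parse_and_filter_reads <- function(reads, ts_oligo = NULL, q_min = 25,
                                   max_edit = 5L) {
  if (nrow(reads) == 0L) {
    warn("no reads supplied")
    attr(reads, "filter_log") <- c(low_quality = 0L, ts_mismatch = 0L)
    return(reads)
  }
  pass_q <- reads$mean_q > q_min
  if (!is.null(ts_oligo)) {
    if (!nzchar(ts_oligo)) abort("ts_oligo must be non-empty when supplied")
    if (!"ts_suffix" %in% names(reads)) {
      abort("reads need a 'ts_suffix' column for template-switch matching")
    }
    pass_ts <- edit_distance(reads$ts_suffix, ts_oligo) <= max_edit
  } else {
    pass_ts <- rep(TRUE, nrow(reads))
  }
  out <- reads[pass_q & pass_ts, , drop = FALSE]
  attr(out, "filter_log") <- c(
    low_quality = sum(!pass_q),
    ts_mismatch = sum(pass_q & !pass_ts))
  out
}

#' Collapse UMIs into molecule counts
#'
#' Within each (variant, fraction) group, unique molecular identifiers are
#' clustered: exact duplicates merge, then any UMI within Hamming distance 1
#' of a more abundant UMI is greedily merged into it (UMIs visited in
#' descending read-count order, ties broken by lexicographic UMI). The
#' per-group molecule count is the number of resulting clusters. This is the
#' deterministic directional-clustering contract used in place of an external
#' UMI clustering tool.
#'
#' @param reads Tibble with columns `variant_id`, `fraction_id`, `umi`
#'   (fixed-length strings).
#' @param fractions Optional [fraction_specs()] tibble to attach to the
#'   result.
#' @param replicate_id,cell_type Labels stored on the count matrix.
#' @return A `fraction_counts` object (see [fraction_counts()]).
#' @export
collapse_umis <- function(reads, fractions = NULL, replicate_id = "rep1",
                          cell_type = "synthetic") {
  if (!"variant_id" %in% names(reads)) {
    if (!"variable_region" %in% names(reads)) {
      abort("reads need a 'variant_id' or 'variable_region' column")
    }
    reads <- mutate(reads, variant_id = .data$variable_region)
  }
  if (length(unique(nchar(reads$umi))) > 1L) {
    abort("ragged UMI lengths: all UMIs must have the same length")
  }
  counts <- reads |>
    group_by(.data$variant_id, .data$fraction_id) |>
    summarise(count = cluster_umis(.data$umi), .groups = "drop")
  fraction_counts(counts, fractions = fractions,
                  replicate_id = replicate_id, cell_type = cell_type)
}

# Number of directional Hamming-1 clusters among a vector of UMIs.
cluster_umis <- function(umis) {
  tab <- table(umis)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  n_clusters <- 0L
  for (u in names(tab)[ord]) {
    nb <- hamming1_neighbors(u)
    merged <- FALSE
    for (v in nb[-1]) {
      if (!is.null(seen[[v]])) { merged <- TRUE; break }
    }
    if (!merged) n_clusters <- n_clusters + 1L
    # merged UMIs stay visible so lower-count UMIs can chain through them
    seen[[u]] <- TRUE
  }
  n_clusters
}

# A UMI itself plus all strings at Hamming distance exactly 1.
hamming1_neighbors <- function(u) {
  chars <- strsplit(u, "")[[1]]
  bases <- c("A", "C", "G", "T")
  out <- character(1L + 3L * length(chars))
  out[1] <- u
  k <- 1L
  for (i in seq_along(chars)) {
    for (b in bases[bases != chars[i]]) {
      k <- k + 1L
      v <- chars; v[i] <- b
      out[k] <- paste(v, collapse = "")
    }
  }
  out
}

#' Read random-end MPRA reads from FASTQ
#'
#' Read 1 carries the reverse complement of the variable 5'UTR followed by
#' the reverse complement of the template-switching oligo; read 2 carries the
#' UMI. This reader reorients read 1, splits off the TS-adjacent suffix, and
#' returns the read tibble consumed by [parse_and_filter_reads()].
#'
#' @param fastq1,fastq2 Paths to read-1 and read-2 FASTQ files.
#' @param variable_length Length of the variable 5'UTR region.
#' @param fraction_id Fraction label assigned to all reads in the file pair.
#' @return Read tibble with `variable_region`, `ts_suffix`, `umi`, `mean_q`,
#'   `fraction_id`.
#' @export
read_mpra_fastq <- function(fastq1, fastq2, variable_length = 25L,
                            fraction_id = "f1") {
  r1 <- Biostrings::readQualityScaledDNAStringSet(fastq1)
  r2 <- Biostrings::readQualityScaledDNAStringSet(fastq2)
  if (length(r1) != length(r2)) abort("read 1 / read 2 length mismatch")
  mean_q <- vapply(methods::as(Biostrings::quality(r1), "IntegerList"),
                   mean, numeric(1))
  fwd <- as.character(Biostrings::reverseComplement(
    methods::as(r1, "DNAStringSet")))
  tibble(
    variable_region = substring(fwd, nchar(fwd) - variable_length + 1L,
                                nchar(fwd)),
    ts_suffix = substring(fwd, 1L, nchar(fwd) - variable_length),
    umi = as.character(methods::as(r2, "DNAStringSet")),
    mean_q = mean_q,
    fraction_id = fraction_id)
}
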