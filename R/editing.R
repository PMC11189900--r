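#' Gene-editing efficiency from aligned amplicon reads
#'
#' The NHEJ editing-frequency statistic: the percentage of reads containing
#' insertions or deletions that touch the window around the expected
#' nuclease breakpoint, among reads passing mapping and base-quality
#' filters. The denominator keeps reads with MAPQ > 20 and mean quality
#' > 30; the numerator is the subset with any indel interval intersecting
#' `[breakpoint - window_half, breakpoint + window_half]` (a 10-base window
#' at the default `window_half = 5`; intervals are 0-based half-open
#' `[start, end)` on the amplicon).
#'
#' @param aligned_reads Tibble with one row per read: `mapq`, `mean_q` and
#'   an `indels` column — either a list-column of two-column matrices /
#'   data.frames (`start`, `end`) or a compact string `"s1:e1,s2:e2"`
#'   (empty string or `NA` = no indels).
#' @param breakpoint Expected cut position (0-based) on the amplicon.
#' @param window_half Half-width of the breakpoint window (default 5).
#' @param min_mapq,min_q Filter thresholds (exclusive; defaults 20 and 30).
#' @return Editing efficiency as a percentage.
#' @export
editing_efficiency <- function(aligned_reads, breakpoint, window_half = 5L,
                               min_mapq = 20, min_q = 30) {
  pass <- aligned_reads$mapq > min_mapq & aligned_reads$mean_q > min_q
  if (!any(pass)) abort("no read passes the MAPQ/quality filters")
  reads <- aligned_reads[pass, , drop = FALSE]
  lo <- breakpoint - window_half
  hi <- breakpoint + window_half
  intervals <- parse_indels(reads$indels)
  edited <- vapply(intervals, function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
    any(iv[, 1] < hi & iv[, 2] > lo)
  }, logical(1))
  100 * sum(edited) / nrow(reads)
}

# Normalizes the indels column into a list of 2-column matrices.
parse_indels <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(iv) {
      if (is.null(iv) || length(iv) == 0L) return(NULL)
      as.matrix(as.data.frame(iv))
    }))
  }
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, ",")[[1]], ":")
    matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  })
}

#' Derive indel intervals from SAM records
#'
#' Thin reader for tab-delimited SAM alignments: extracts MAPQ, mean base
#' quality, and CIGAR-derived indel intervals in 0-based reference
#' coordinates relative to the amplicon (POS-adjusted), producing the table
#' [editing_efficiency()] consumes. Alignment itself is upstream of this
#' package.
#'
#' @param path Path to a SAM file (header lines ignored).
#' @return Tibble with `read_id`, `mapq`, `mean_q`, `indels` (compact
#'   string encoding).
#' @export
read_aligned_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    qual <- f[11]
    mean_q <- if (identical(qual, "*")) NA_real_ else {
      mean(as.integer(charToRaw(qual)) - 33L)
    }
    tibble(read_id = f[1], mapq = as.numeric(f[5]), mean_q = mean_q,
           indels = cigar_indel_string(f[6], as.integer(f[4]) - 1L))
  })
  bind_rows(rows)
}

# 0-based reference-space indel intervals from a CIGAR string; insertions
# get zero-width-plus-one intervals at their anchor so window intersection
# still detects them.
cigar_indel_string <- function(cigar, ref_start) {
  if (identical(cigar, "*")) return("")
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  kinds <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  pos <- ref_start
  out <- character(0)
  for (i in seq_along(kinds)) {
    k <- kinds[i]; n <- lens[i]
    if (k %in% c("M", "=", "X", "N")) {
      pos <- pos + n
    } else if (k == "D") {
      out <- c(out, sprintf("%d:%d", pos, pos + n))
      pos <- pos + n
    } else if (k == "I") {
      out <- c(out, sprintf("%d:%d", pos, pos + 1L))
    }
    # S/H/P consume neither reference position nor create intervals
  }
  paste(out, collapse = ",")
}

#' Kozak-normalized editing-efficiency summaries
#'
#' Normalizes each editing measurement to the minimal strong-Kozak control
#' at the same (dosage, replicate), then summarizes each 5'UTR by the mean
#' and standard deviation of its normalized efficiencies across all
#' retained (dosage x replicate) points — n = 8 for 2 replicates x 4
#' dosages, n = 6 when one dosage is excluded. Exclusions (e.g. failed
#' low-dose transfections) are explicit, never auto-detected.
#'
#' @param records Tibble with `utr_id`, `dosage_pmol`, `replicate`,
#'   `efficiency_percent` (and optionally `target_gene`, `cell_line`,
#'   which are treated as grouping columns).
#' @param control_id The control UTR id (default `"StrongKozak"`).
#' @param exclusions Optional tibble of points to drop before
#'   normalization, with columns `utr_id`, `dosage_pmol` (and optionally
#'   `replicate`).
#' @return Tibble with one row per (group x) `utr_id`: `mean_normalized`,
#'   `sd_normalized`, `n`.
#' @export
kozak_normalize <- function(records, control_id = "StrongKozak",
                            exclusions = NULL) {
  stopifnot(all(c("utr_id", "dosage_pmol", "replicate",
                  "efficiency_percent") %in% names(records)))
  if (any(records$efficiency_percent < 0 |
            records$efficiency_percent > 100)) {
    abort("efficiency_percent must lie in [0, 100]")
  }
  groups <- intersect(c("target_gene", "cell_line"), names(records))
  if (!is.null(exclusions)) {
    key <- c("utr_id", "dosage_pmol",
             intersect("replicate", names(exclusions)))
    records <- dplyr::anti_join(records, exclusions, by = key)
  }
  ctrl <- records |>
    filter(.data$utr_id == control_id) |>
    select(all_of(c(groups, "dosage_pmol", "replicate",
                    "efficiency_percent"))) |>
    rename(control_efficiency = "efficiency_percent")
  if (nrow(ctrl) == 0L) {
    abort(sprintf("control '%s' not found", control_id))
  }
  joined <- records |>
    left_join(ctrl, by = c(groups, "dosage_pmol", "replicate"))
  miss <- joined[is.na(joined$control_efficiency), , drop = FALSE]
  if (nrow(miss)) {
    abort(sprintf(
      "control '%s' missing at dosage %g pmol (replicate %s)",
      control_id, miss$dosage_pmol[1], as.character(miss$replicate[1])))
  }
  if (any(joined$control_efficiency <= 0)) {
    abort("control efficiency must be positive at every retained point")
  }
  joined |>
    mutate(normalized = .data$efficiency_percent /
             .data$control_efficiency) |>
    group_by(across(all_of(c(groups, "utr_id")))) |>
    summarise(mean_normalized = mean(.data$normalized),
              sd_normalized = sd(.data$normalized),
              n = n(), .groups = "drop")
}
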