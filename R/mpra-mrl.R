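#' Polysome fraction descriptions
#'
#' Builds the tibble of fraction metadata used by [fraction_counts()]:
#' one row per fraction with its assigned ribosome load and a flag for the
#' ribosome-free fraction. MRL only considers fractions with one or more
#' ribosomes; the free fraction is carried through for the free-to-total
#' analyses but excluded from MRL sums. The number of collected fractions
#' and the load of the heaviest are experiment configuration; the default is
#' loads 1..8.
#'
#' @param loads Numeric vector of ribosome loads for the loaded fractions.
#' @param free Include a ribosome-free fraction (`load = 0`)?
#' @return Tibble with `fraction_id`, `ribosome_load`, `is_free`.
#' @export
fraction_specs <- function(loads = 1:8, free = FALSE) {
  if (any(loads < 1)) abort("loaded fractions must have ribosome_load >= 1")
  out <- tibble(fraction_id = paste0("rib", loads),
                ribosome_load = as.numeric(loads), is_free = FALSE)
  if (free) {
    out <- bind_rows(
      tibble(fraction_id = "free", ribosome_load = 0, is_free = TRUE), out)
  }
  out
}

#' Variant-by-fraction UMI count container
#'
#' A `fraction_counts` object is a long tibble (`variant_id`, `fraction_id`,
#' `count`) with the fraction metadata, replicate and cell-type labels
#' attached as attributes. Counts must be non-negative; missing
#' (variant, fraction) cells are treated as zero.
#'
#' @param counts Long tibble with `variant_id`, `fraction_id`, `count`.
#' @param fractions A [fraction_specs()] tibble; defaults to loads named in
#'   `counts` parsed as `rib<k>` plus `free`.
#' @param replicate_id,cell_type Provenance labels.
#' @return A `fraction_counts` tibble.
#' @export
fraction_counts <- function(counts, fractions = NULL, replicate_id = "rep1",
                            cell_type = "synthetic") {
  stopifnot(all(c("variant_id", "fraction_id", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    abort("counts must be non-negative integers")
  }
  if (is.null(fractions)) {
    ids <- unique(counts$fraction_id)
    loads <- ifelse(ids == "free", 0, suppressWarnings(
      as.numeric(sub("^rib", "", ids))))
    if (anyNA(loads)) {
      abort("cannot infer ribosome loads from fraction ids; pass `fractions`")
    }
    fractions <- tibble(fraction_id = ids, ribosome_load = loads,
                        is_free = loads == 0)
  }
  if (anyDuplicated(fractions$fraction_id)) {
    abort("fraction ids must be unique")
  }
  unknown <- setdiff(counts$fraction_id, fractions$fraction_id)
  if (length(unknown)) {
    abort(sprintf("counts name unknown fraction '%s'", unknown[1]))
  }
  out <- as_tibble(counts[c("variant_id", "fraction_id", "count")])
  attr(out, "fractions") <- as_tibble(fractions)
  attr(out, "replicate_id") <- replicate_id
  attr(out, "cell_type") <- cell_type
  class(out) <- c("fraction_counts", class(out))
  out
}

#' @export
print.fraction_counts <- function(x, ...) {
  fr <- attr(x, "fractions")
  cat(sprintf(
    "<fraction_counts> %d variants x %d fractions (replicate %s, %s)\n",
    length(unique(x$variant_id)), nrow(fr), attr(x, "replicate_id"),
    attr(x, "cell_type")))
  NextMethod()
}

#' Mean ribosome load per variant
#'
#' Computes MRL from UMI counts on all loaded polysome fractions by
#' 1) normalizing each fraction library to its total number of reads,
#' 2) summing the product of each fraction's normalized count with its
#' associated number of ribosomes, and 3) dividing by the unweighted sum of
#' normalized counts across all fractions:
#' \deqn{MRL_v = \frac{\sum_f (c_{vf}/N_f)\, r_f}{\sum_f (c_{vf}/N_f)}}
#' with sums over non-free fractions \eqn{f} and \eqn{N_f = \sum_v c_{vf}}.
#' Ribosome-free fractions are excluded; variants with all-zero loaded
#' counts are dropped. The result is invariant to rescaling any single
#' fraction's counts.
#'
#' @param counts A [fraction_counts()] object.
#' @return Tibble with `variant_id`, `mrl`, `total_reads` (sum of loaded
#'   UMI counts) and `replicate_id`.
#' @examples
#' fc <- fraction_counts(
#'   tibble::tibble(variant_id = "v1", fraction_id = c("rib1", "rib2", "rib3"),
#'                  count = c(10, 10, 40)),
#'   fractions = fraction_specs(1:3))
#' # with equal fraction depths this is (1*10 + 2*10 + 3*40) / 60
#' compute_mrl(fc)
#' @export
compute_mrl <- function(counts) {
  fr <- attr(counts, "fractions")
  if (is.null(fr)) abort("`counts` must be a fraction_counts object")
  loaded <- fr[!fr$is_free, ]
  x <- counts[counts$fraction_id %in% loaded$fraction_id, , drop = FALSE]
  totals <- x |> group_by(.data$fraction_id) |>
    summarise(N = sum(.data$count), .groups = "drop")
  zero <- totals$fraction_id[totals$N == 0]
  missing_fr <- setdiff(loaded$fraction_id, totals$fraction_id)
  if (length(c(zero, missing_fr))) {
    abort(sprintf("fraction '%s' has zero total counts",
                  c(zero, missing_fr)[1]))
  }
  x |>
    left_join(totals, by = "fraction_id") |>
    left_join(loaded[c("fraction_id", "ribosome_load")], by = "fraction_id") |>
    mutate(norm = .data$count / .data$N) |>
    group_by(.data$variant_id) |>
    summarise(
      mrl = sum(.data$norm * .data$ribosome_load) / sum(.data$norm),
      total_reads = sum(.data$count),
      .groups = "drop") |>
    filter(.data$total_reads > 0) |>
    mutate(replicate_id = attr(counts, "replicate_id") %||% "rep1")
}

#' Filter by per-replicate depth and average MRL across replicates
#'
#' Keeps variants whose total read count is at least `min_reads` in every
#' replicate (the per-replicate sum across fractions), then averages MRL
#' across replicates weighted by each replicate's total UMI reads.
#'
#' @param tables A list of per-replicate MRL tibbles from [compute_mrl()]
#'   (or a single tibble).
#' @param min_reads Minimum reads required in each replicate (default 100).
#' @return Tibble with `variant_id`, `mrl` (weighted average), `reads`
#'   (combined depth across replicates) and `n_replicates`.
#' @export
filter_and_average_replicates <- function(tables, min_reads = 100) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) < 1L) abort("need at least one replicate")
  all_reps <- bind_rows(tables)
  n_rep <- length(tables)
  out <- all_reps |>
    group_by(.data$variant_id) |>
    filter(n() == n_rep, all(.data$total_reads >= min_reads)) |>
    summarise(
      mrl = sum(.data$mrl * .data$total_reads) / sum(.data$total_reads),
      reads = sum(.data$total_reads),
      n_replicates = n(),
      .groups = "drop")
  if (nrow(out) == 0L) {
    warn("no variant passes the read filter in all replicates")
  }
  out
}

#' Attach sequences to an MRL table
#'
#' @param mrl_table Tibble with a `variant_id` column.
#' @param lib A [utr_library()] whose `id` matches `variant_id`.
#' @return The MRL table with `sequence`, `architecture`, `prefix`,
#'   `cds_offset` columns joined in.
#' @export
join_sequences <- function(mrl_table, lib) {
  inner_join(mrl_table,
             rename(as_tibble(lib), variant_id = "id"),
             by = "variant_id")
}

#' Read / write fraction count tables
#'
#' TSV layout: columns `variant_id`, `fraction_id`, `count`; fraction loads
#' are inferred from `rib<k>` / `free` ids unless `fractions` is given.
#'
#' @param path File path.
#' @param fractions Optional [fraction_specs()] tibble.
#' @param replicate_id,cell_type Provenance labels.
#' @param counts A `fraction_counts` object to write.
#' @return A `fraction_counts` (reader) or `path` invisibly (writer).
#' @export
read_fraction_counts <- function(path, fractions = NULL,
                                 replicate_id = "rep1",
                                 cell_type = "unknown") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fraction_counts(as_tibble(df), fractions = fractions,
                  replicate_id = replicate_id, cell_type = cell_type)
}

#' @rdname read_fraction_counts
#' @export
write_fraction_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
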