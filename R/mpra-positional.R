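#' Positional motif effect on MRL
#'
#' For each transcript position `p`, takes the median MRL of all variants in
#' which the motif occurs at `p`, normalized to the library-wide median MRL,
#' optionally with a two-sided Mann-Whitney U p-value against the variants
#' without a motif at `p`. This reproduces the positional analyses of
#' upstream AUGs and 5-nt oligopyrimidine tracts: positions are 0-based from
#' the transcript start (the first IVT `G`).
#'
#' @param table An MRL table with sequence metadata (see [join_sequences()]):
#'   columns `mrl`, `sequence`, `prefix`, `cds_offset`.
#' @param motif Either one of the built-ins `"uaug"` (ATG upstream of the
#'   main ORF) or `"pyr5"` (5-nt C/T tract), or a predicate
#'   `function(transcripts, position)` returning a logical vector.
#' @param positions Integer vector of 0-based positions to evaluate
#'   (default: all positions fully inside the transcript for the motif
#'   width).
#' @param min_sequences Positions matched by fewer sequences are reported
#'   with `normalized_median = NA` (default 50).
#' @param test Compute Mann-Whitney p-values (default TRUE).
#' @param frame Optionally restrict `"uaug"` hits to `"in_frame"` or
#'   `"out_of_frame"` occurrences.
#' @return A `positional_effect` tibble with `position`, `n`,
#'   `normalized_median` and (optionally) `p_value`, carrying the library
#'   median as an attribute.
#' @export
positional_median_effect <- function(table, motif = "uaug",
                                     positions = NULL, min_sequences = 50L,
                                     test = TRUE, frame = NULL) {
  stopifnot(all(c("mrl", "sequence") %in% names(table)))
  transcripts <- paste0(table$prefix %||% "", table$sequence)
  cds_offset <- table$cds_offset %||% nchar(transcripts)
  width <- if (identical(motif, "pyr5")) 5L else 3L
  pred <- motif_predicate(motif, cds_offset, frame)
  if (is.null(positions)) {
    positions <- 0:(min(nchar(transcripts)) - width)
  }
  lib_median <- median(table$mrl)
  rows <- lapply(positions, function(p) {
    hit <- pred(transcripts, p)
    n_hit <- sum(hit)
    if (n_hit < min_sequences) {
      return(tibble(position = p, n = n_hit, normalized_median = NA_real_,
                    p_value = NA_real_))
    }
    pv <- if (test && n_hit < length(hit)) {
      suppressWarnings(
        wilcox.test(table$mrl[hit], table$mrl[!hit])$p.value)
    } else NA_real_
    tibble(position = p, n = n_hit,
           normalized_median = median(table$mrl[hit]) / lib_median,
           p_value = pv)
  })
  out <- bind_rows(rows)
  if (!test) out$p_value <- NULL
  attr(out, "library_median") <- lib_median
  attr(out, "motif") <- if (is.character(motif)) motif else "custom"
  class(out) <- c("positional_effect", class(out))
  out
}

# Builds a predicate function(transcripts, p) -> logical for a motif spec.
motif_predicate <- function(motif, cds_offset, frame = NULL) {
  if (is.function(motif)) return(motif)
  if (identical(motif, "uaug")) {
    function(transcripts, p) {
      hit <- substring(transcripts, p + 1L, p + 3L) == "ATG" &
        p + 3L <= cds_offset
      if (!is.null(frame)) {
        in_frame <- (cds_offset - p) %% 3L == 0L
        hit <- hit & if (frame == "in_frame") in_frame else !in_frame
      }
      hit
    }
  } else if (identical(motif, "pyr5")) {
    function(transcripts, p) {
      !grepl("[AG]", substring(transcripts, p + 1L, p + 5L))
    }
  } else {
    abort("motif must be 'uaug', 'pyr5', or a predicate function")
  }
}

#' @export
#' @rdname positional_median_effect
#' @param object A `positional_effect` tibble.
#' @param ... Unused.
autoplot.positional_effect <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$normalized_median), ],
                  ggplot2::aes(x = .data$position,
                               y = .data$normalized_median)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position from transcript start (nt)",
                  y = "median MRL / library median",
                  title = sprintf("positional %s effect",
                                  attr(object, "motif"))) +
    ggplot2::theme_minimal()
}
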