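#' Log-scaled k-mer count features
#'
#' Counts every k-mer for `k = k_min..k_max` (overlapping occurrences) and
#' returns `log2(1 + count)` in a fixed ordering: ascending `k`,
#' lexicographic within each `k`. For `k = 2..6` the dimension is
#' `sum(4^(2:6)) = 5456`.
#'
#' @param sequence A single sequence string.
#' @param k_min,k_max Smallest and largest k-mer size.
#' @return Named numeric vector of length `sum(4^(k_min:k_max))`.
#' @examples
#' f <- kmer_log_features("AAAA", k_min = 2, k_max = 2)
#' f[["AA"]]  # log2(1 + 3)
#' @export
kmer_log_features <- function(sequence, k_min = 2L, k_max = 6L) {
  m <- kmer_feature_matrix(sequence, k_min = k_min, k_max = k_max,
                           sparse = FALSE)
  setNames(as.numeric(m[1, ]), colnames(m))
}

#' k-mer feature matrix for a set of sequences
#'
#' Matrix version of [kmer_log_features()]; rows are sequences, columns the
#' fixed k-mer ordering. Counting uses
#' [Biostrings::oligonucleotideFrequency()].
#'
#' @param sequences Character vector of sequences (all `>= k_max` long).
#' @inheritParams kmer_log_features
#' @param sparse Return a `dgCMatrix` (default) or a dense matrix.
#' @return Sequences x k-mers matrix of `log2(1 + count)`.
#' @export
kmer_feature_matrix <- function(sequences, k_min = 2L, k_max = 6L,
                                sparse = TRUE) {
  if (k_min > k_max) abort("k_min must be <= k_max")
  sequences <- normalize_dna(sequences)
  if (any(nchar(sequences) < k_max)) {
    abort(sprintf("all sequences must be at least k_max = %d long", k_max))
  }
  n <- length(sequences)
  dims <- 4L^(k_min:k_max)
  offsets <- cumsum(c(0L, dims))[seq_along(dims)]
  p_total <- sum(dims)
  chunk <- 10000L
  trip_i <- list(); trip_j <- list(); trip_x <- list(); nb <- 0L
  for (start in seq.int(1L, n, chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    ss <- Biostrings::DNAStringSet(sequences[idx])
    for (ki in seq_along(dims)) {
      # columns of oligonucleotideFrequency are in lexicographic ACGT order
      counts <- Biostrings::oligonucleotideFrequency(ss, width = k_min + ki - 1L)
      nz <- which(counts != 0L)
      nb <- nb + 1L
      trip_i[[nb]] <- idx[(nz - 1L) %% length(idx) + 1L]
      trip_j[[nb]] <- offsets[ki] + (nz - 1L) %/% length(idx) + 1L
      trip_x[[nb]] <- log2(1 + counts[nz])
    }
  }
  cn <- unlist(lapply(k_min:k_max, all_kmers))
  out <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_x), dims = c(n, p_total),
                              dimnames = list(names(sequences), cn))
  if (sparse) out else as.matrix(out)
}

#' Positional 3-mer indicator features
#'
#' One binary indicator per (offset, 3-mer) pair: for a sequence of length
#' `L` there are `(L - 2) * 64` features, of which exactly `L - 2` are 1.
#' Feature order: offsets ascending, 3-mers lexicographic within an offset;
#' names are `"o<offset>_<3mer>"` with 0-based offsets.
#'
#' @param sequence A single sequence (length `>= 3`).
#' @return Named numeric 0/1 vector.
#' @export
positional_3mer_features <- function(sequence) {
  m <- positional_3mer_matrix(sequence, sparse = FALSE)
  setNames(as.numeric(m[1, ]), colnames(m))
}

#' Positional 3-mer feature matrix
#'
#' Sparse matrix version of [positional_3mer_features()] for equal-length
#' sequences.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param sparse Return a `dgCMatrix` (default) or dense matrix.
#' @return Sequences x `(L-2)*64` indicator matrix.
#' @export
positional_3mer_matrix <- function(sequences, sparse = TRUE) {
  sequences <- normalize_dna(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort("sequences must all have the same length")
  if (L < 3L) abort("sequences must be at least 3 nt long")
  n <- length(sequences)
  n_off <- L - 2L
  kmers <- all_kmers(3L)
  cols <- integer(n * n_off)
  for (o in seq_len(n_off)) {
    words <- substring(sequences, o, o + 2L)
    cols[(o - 1L) * n + seq_len(n)] <- (o - 1L) * 64L + match(words, kmers)
  }
  rows <- rep(seq_len(n), times = n_off)
  cn <- paste0("o", rep(0:(n_off - 1L), each = 64L), "_", rep(kmers, n_off))
  m <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(n, n_off * 64L),
                            dimnames = list(names(sequences), cn))
  if (sparse) m else as.matrix(m)
}

# All k-mers over ACGT in lexicographic order.
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1L) for (i in 2:k) out <- as.vector(t(outer(out, bases, paste0)))
  out
}

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance between two strings,
#' as used for matching observed read tails against the expected
#' template-switching oligo. Thin wrapper over [utils::adist()]; vectorized
#' over its arguments.
#'
#' @param a,b Character vectors (recycled).
#' @return Integer vector of distances.
#' @examples
#' edit_distance("AAA", "AAT")
#' @export
edit_distance <- function(a, b) {
  if (length(b) == 1L) return(as.integer(adist(a, b)[, 1]))
  if (length(a) == 1L) return(as.integer(adist(a, b)[1, ]))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- adist(a[i], b[i])[1, 1]
  out
}
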