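#' One-hot encode 5'UTR sequences
#'
#' Encodes a sequence as an `L x 4` matrix over the fixed channel order
#' `(A, C, G, T)`, zero-padded on the left to reach `model_input_length`
#' (shorter inputs are padded, matching how shorter UTRs are fed to a fixed
#' input-width predictor).
#'
#' @param sequence A single sequence string, or a `utr_library` row subset
#'   (in which case the variable region is encoded).
#' @param model_input_length Required input width `>=` sequence length.
#' @return A `model_input_length x 4` 0/1 matrix with attribute `pad_columns`
#'   (number of all-zero left rows) and column names `A,C,G,T`.
#' @examples
#' m <- one_hot_encode("ACGT", 4)
#' all(diag(m[, c("A", "C", "G", "T")]) == 1)
#' @export
one_hot_encode <- function(sequence, model_input_length = NULL) {
  if (is_tibble(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  sequence <- normalize_dna(sequence)
  L <- nchar(sequence)
  if (is.null(model_input_length)) model_input_length <- L
  if (L > model_input_length) {
    abort(sprintf("sequence length %d exceeds model input length %d",
                  L, model_input_length))
  }
  pad <- as.integer(model_input_length - L)
  m <- matrix(0, model_input_length, 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  idx <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  m[cbind(pad + seq_len(L), idx)] <- 1
  attr(m, "pad_columns") <- pad
  m
}

#' Batch one-hot encoding to a 3-d array
#'
#' @param sequences Character vector of equal-alphabet sequences.
#' @param model_input_length Input width (default: max sequence length).
#' @return Array of dim `(n, model_input_length, 4)`.
#' @export
one_hot_encode_batch <- function(sequences, model_input_length = NULL) {
  sequences <- normalize_dna(sequences)
  n <- length(sequences)
  lens <- nchar(sequences)
  if (is.null(model_input_length)) model_input_length <- max(lens)
  if (any(lens > model_input_length)) {
    abort("sequence longer than model input length")
  }
  X <- array(0, c(n, model_input_length, 4L))
  chars <- strsplit(sequences, "")
  for (i in seq_len(n)) {
    idx <- match(chars[[i]], c("A", "C", "G", "T"))
    pad <- model_input_length - lens[i]
    X[cbind(i, pad + seq_along(idx), idx)] <- 1
  }
  X
}

#' Decode a one-hot (or relaxed probability) matrix back to a sequence
#'
#' Takes the per-position argmax over the `(A, C, G, T)` channels; all-zero
#' left padding rows are skipped.
#'
#' @param m An `L x 4` matrix.
#' @return A sequence string.
#' @export
one_hot_decode <- function(m) {
  keep <- rowSums(abs(m)) > 0
  if (!any(keep)) return("")
  m <- m[which(keep)[1]:nrow(m), , drop = FALSE]
  paste(c("A", "C", "G", "T")[max.col(m, ties.method = "first")],
        collapse = "")
}
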