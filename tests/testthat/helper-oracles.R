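# Independent brute-force oracles used to cross-check the implementation.

# Levenshtein distance by textbook dynamic programming.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# Position-by-position motif scan.
brute_scan <- function(transcript, codons, cds_offset) {
  chars <- strsplit(transcript, "")[[1]]
  hits <- integer(0)
  for (p in 0:(nchar(transcript) - 3)) {
    if (p + 3 > cds_offset) break
    if (paste(chars[(p + 1):(p + 3)], collapse = "") %in% codons) {
      hits <- c(hits, p)
    }
  }
  hits
}

# Brute-force pyrimidine tract scan.
brute_tracts <- function(transcript, len) {
  chars <- strsplit(transcript, "")[[1]]
  out <- integer(0)
  if (length(chars) < len) return(out)
  for (p in 0:(length(chars) - len)) {
    if (all(chars[(p + 1):(p + len)] %in% c("C", "T"))) out <- c(out, p)
  }
  out
}

# The three-step MRL formula written independently: normalize fractions,
# weight by loads, divide by the unweighted normalized sum.
brute_mrl <- function(count_matrix, loads) {
  N <- colSums(count_matrix)
  norm <- sweep(count_matrix, 2, N, "/")
  num <- as.numeric(norm %*% loads)
  den <- rowSums(norm)
  num / den
}

# random count matrix wrapped as a fraction_counts object
random_fraction_counts <- function(n_var, loads = 1:8, max_count = 50) {
  m <- matrix(rpois(n_var * length(loads), max_count / 2) + 1L,
              n_var, length(loads))
  counts <- tibble::tibble(
    variant_id = rep(sprintf("v%03d", seq_len(n_var)), length(loads)),
    fraction_id = rep(paste0("rib", loads), each = n_var),
    count = as.integer(m))
  list(fc = fraction_counts(counts, fractions = fraction_specs(loads)),
       matrix = m, loads = loads)
}

# mean pairwise normalized edit distance of a set of sequences
mean_pairwise_norm_edit <- function(seqs) {
  d <- utils::adist(seqs)
  mean(d[upper.tri(d)]) / nchar(seqs[1])
}

# a tiny MRL table from the planted model
planted_table <- function(n, seed, architecture = "random_end_25",
                          noise = TRUE, reads = NULL) {
  lib <- generate_library(n, architecture = architecture, seed = seed)
  mrl <- ground_truth_mrl(lib, with_noise = noise, seed = seed + 1L)
  if (is.null(reads)) reads <- rpois(n, 500) + 1L
  dplyr::mutate(
    tibble::tibble(variant_id = lib$id, sequence = lib$sequence,
                   mrl = mrl, reads = reads),
    prefix = lib$prefix, cds_offset = lib$cds_offset,
    architecture = lib$architecture)
}
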