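#' Depth-ranked train/validation/test split
#'
#' Sorts variants by read depth (descending, ties broken by variant id for
#' determinism), holds out the top `k_test` for testing and the next `k_val`
#' for validation/early stopping; the remainder trains the model.
#'
#' @param table An MRL table with `variant_id`, `reads` (or `total_reads`),
#'   and the columns the models need (`sequence`, `mrl`).
#' @param k_test,k_val Hold-out sizes (defaults 2000/2000).
#' @return An `mrl_split` list with tibbles `train`, `validation`, `test`.
#' @export
make_split <- function(table, k_test = 2000L, k_val = 2000L) {
  depth_col <- if ("reads" %in% names(table)) "reads" else "total_reads"
  if (!depth_col %in% names(table)) abort("table needs a read-depth column")
  if (nrow(table) <= k_test + k_val) {
    abort(sprintf("table has %d variants; need more than k_test + k_val = %d",
                  nrow(table), k_test + k_val))
  }
  ord <- order(-table[[depth_col]], table$variant_id, method = "radix")
  table <- table[ord, , drop = FALSE]
  structure(list(
    test = table[seq_len(k_test), , drop = FALSE],
    validation = table[k_test + seq_len(k_val), , drop = FALSE],
    train = table[-(seq_len(k_test + k_val)), , drop = FALSE]),
    class = "mrl_split")
}

#' @export
print.mrl_split <- function(x, ...) {
  cat(sprintf("<mrl_split> train %d / validation %d / test %d variants\n",
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Squared Pearson correlation
#'
#' The r-squared used for predictor evaluation and cross-replicate
#' agreement: the square of the Pearson correlation between two vectors
#' (sign-blind; distinct from the coefficient of determination about the
#' identity line).
#'
#' @param predicted,measured Equal-length numeric vectors.
#' @return A number in `[0, 1]`.
#' @export
evaluate_r2 <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 2L) {
    abort("need two equal-length vectors of length >= 2")
  }
  if (sd(predicted) == 0 || sd(measured) == 0) {
    abort("undefined correlation: an input has zero variance")
  }
  cor(predicted, measured)^2
}

#' Positional 3-mer linear MRL model
#'
#' Least squares (with a tiny ridge stabilizer for the structural
#' collinearity of positional indicators) of MRL on the
#' [positional_3mer_matrix()] features, one weight per (offset, 3-mer).
#' Companion analyses compare weight vectors across replicates by Pearson
#' correlation ([compare_weights()]).
#'
#' @param table Tibble with `sequence` and `mrl` (equal-length sequences).
#' @param ridge Stabilizer added to the normal-equation diagonal (relative
#'   to `n`); default `1e-6`.
#' @return A `positional_3mer_model` with `weights` ((L-2) x 64 matrix),
#'   `intercept`, and the flat named weight vector `coef`.
#' @export
train_positional_3mer <- function(table, ridge = 1e-6) {
  X <- positional_3mer_matrix(table$sequence)
  y <- table$mrl
  n <- nrow(X); p <- ncol(X)
  xbar <- Matrix::colMeans(X)
  ybar <- mean(y)
  XtX <- as.matrix(Matrix::crossprod(X)) / n - tcrossprod(xbar)
  Xty <- as.numeric(Matrix::crossprod(X, y)) / n - xbar * ybar
  w <- solve(XtX + diag(ridge, p), Xty)
  w <- as.numeric(w)
  names(w) <- colnames(X)
  L <- unique(nchar(table$sequence))
  structure(list(
    coef = w,
    weights = matrix(w, nrow = L - 2L, ncol = 64L, byrow = TRUE,
                     dimnames = list(paste0("o", 0:(L - 3L)), all_kmers(3L))),
    intercept = ybar - sum(xbar * w),
    sequence_length = L),
    class = "positional_3mer_model")
}

#' @export
predict_mrl.positional_3mer_model <- function(predictor, sequences) {
  sequences <- sequences_of(sequences)
  X <- positional_3mer_matrix(sequences)
  as.numeric(X %*% predictor$coef) + predictor$intercept
}

#' @export
tidy.positional_3mer_model <- function(x, ...) {
  tibble(term = names(x$coef),
         offset = as.integer(sub("^o(\\d+)_.*$", "\\1", names(x$coef))),
         kmer = sub("^o\\d+_", "", names(x$coef)),
         estimate = unname(x$coef))
}

#' @export
print.positional_3mer_model <- function(x, ...) {
  cat(sprintf("<positional_3mer_model> %dnt sequences, %d weights\n",
              x$sequence_length, length(x$coef)))
  invisible(x)
}

#' Pearson correlation between the weights of two positional 3-mer models
#'
#' @param model_a,model_b Two [train_positional_3mer()] fits on sequences of
#'   the same length.
#' @return Pearson correlation of the flattened weight vectors.
#' @export
compare_weights <- function(model_a, model_b) {
  stopifnot(length(model_a$coef) == length(model_b$coef))
  cor(model_a$coef, model_b$coef)
}

#' Lasso-selected k-mer oracle
#'
#' The independent linear validator for designed sequences. Pipeline:
#' filter the MRL table (minimum read depth; discard sequences containing
#' upstream AUGs; for fixed-end libraries whose constant region ends in `A`,
#' discard sequences starting `TG` to avoid a junction-spanning AUG), build
#' `log2(1 + count)` k-mer features for k = 2..6, fit a Lasso on a seeded
#' random training subset, keep the features with nonzero weights, and refit
#' them by unpenalized least squares ("ridge with alpha = 0") on the full
#' training set.
#'
#' @param table MRL table with `sequence`, `mrl` and a read-depth column;
#'   rows should carry `prefix`/`cds_offset` (see [join_sequences()]) for
#'   the uAUG filter, else sequences are scanned stand-alone.
#' @param min_reads Depth filter (default 250).
#' @param exclude_uaug Drop sequences with any upstream AUG (default TRUE).
#' @param exclude_initial_tg Drop sequences starting `TG` (default: TRUE for
#'   fixed-end tables whose prefix ends in `A`, FALSE otherwise).
#' @param lasso_alpha L1 penalty of the selection stage, in the
#'   `(1/2n)*RSS + alpha*||w||_1` parameterization (default 0.001).
#' @param n_train_subset Size of the seeded random subset used for the Lasso
#'   stage (default 50000; reduced with a warning when fewer sequences
#'   survive the filters).
#' @param test_fraction Fraction held out to report a test-set Pearson r.
#' @param seed Seed for the subset and the train/test split.
#' @return A `kmer_oracle` with `selected_features`, `final_weights`,
#'   `intercept`, `test_r` and the filter specification.
#' @export
train_kmer_oracle <- function(table, min_reads = 250, exclude_uaug = TRUE,
                              exclude_initial_tg = NULL, lasso_alpha = 0.001,
                              n_train_subset = 50000L, test_fraction = 0.2,
                              seed = 1L) {
  depth_col <- if ("reads" %in% names(table)) "reads" else "total_reads"
  keep <- if (depth_col %in% names(table)) {
    table[[depth_col]] >= min_reads
  } else rep(TRUE, nrow(table))
  if (is.null(exclude_initial_tg)) {
    exclude_initial_tg <-
      "architecture" %in% names(table) &&
      any(table$architecture == "fixed_end_50") &&
      "prefix" %in% names(table) &&
      all(substring(table$prefix, nchar(table$prefix)) == "A")
  }
  if (exclude_uaug) {
    has_prefix <- "prefix" %in% names(table)
    transcripts <- if (has_prefix) paste0(table$prefix, table$sequence)
                   else table$sequence
    keep <- keep & !transcript_has_uaug(transcripts)
  }
  if (exclude_initial_tg) {
    keep <- keep & substring(table$sequence, 1L, 2L) != "TG"
  }
  data <- table[keep, , drop = FALSE]
  if (nrow(data) < 50L) abort("too few sequences survive the oracle filters")
  set.seed(seed)
  n <- nrow(data)
  test_idx <- sample.int(n, size = max(1L, round(test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(train_idx) < n_train_subset) {
    warn(sprintf("only %d filtered sequences for the Lasso subset (requested %d)",
                 length(train_idx), n_train_subset))
    subset_idx <- train_idx
  } else {
    subset_idx <- sample(train_idx, n_train_subset)
  }
  X <- kmer_feature_matrix(data$sequence)
  y <- data$mrl
  fit <- glmnet::glmnet(X[subset_idx, , drop = FALSE], y[subset_idx],
                        alpha = 1, lambda = lasso_alpha,
                        standardize = FALSE)
  w <- as.numeric(fit$beta)
  support <- which(w != 0)
  if (length(support) == 0L) {
    abort("no feature survived the Lasso; use a smaller lasso_alpha")
  }
  Xs <- as.matrix(X[train_idx, support, drop = FALSE])
  refit <- stats::lm.fit(cbind(1, Xs), y[train_idx])
  beta <- refit$coefficients
  beta[is.na(beta)] <- 0
  pred_test <- as.numeric(
    as.matrix(X[test_idx, support, drop = FALSE]) %*% beta[-1]) + beta[1]
  structure(list(
    selected_features = colnames(X)[support],
    final_weights = setNames(beta[-1], colnames(X)[support]),
    intercept = unname(beta[1]),
    lasso_alpha = lasso_alpha,
    filter_spec = list(min_reads = min_reads, exclude_uaug = exclude_uaug,
                       exclude_initial_tg = exclude_initial_tg),
    n_lasso_subset = length(subset_idx),
    test_r = if (length(test_idx) >= 3L && sd(pred_test) > 0) {
      cor(pred_test, y[test_idx])
    } else NA_real_,
    seed = seed),
    class = "kmer_oracle")
}

transcript_has_uaug <- function(transcripts) {
  # an AUG anywhere strictly upstream of the main ORF (which starts at the
  # end of the given string)
  n <- nchar(transcripts)
  has <- rep(FALSE, length(transcripts))
  body <- substring(transcripts, 1L, n)  # the UTR is the whole string
  grepl("ATG", body, fixed = TRUE)
}

#' @export
predict_mrl.kmer_oracle <- function(predictor, sequences) {
  sequences <- sequences_of(sequences)
  X <- kmer_feature_matrix(sequences)
  as.numeric(X[, predictor$selected_features, drop = FALSE] %*%
               predictor$final_weights) + predictor$intercept
}

#' @export
print.kmer_oracle <- function(x, ...) {
  cat(sprintf(
    "<kmer_oracle> %d selected k-mers (lasso alpha %g); test Pearson r %.3f\n",
    length(x$selected_features), x$lasso_alpha, x$test_r))
  invisible(x)
}

#' @export
tidy.kmer_oracle <- function(x, ...) {
  tibble(term = names(x$final_weights), estimate = unname(x$final_weights))
}

#' @export
glance.kmer_oracle <- function(x, ...) {
  tibble(n_selected = length(x$selected_features),
         lasso_alpha = x$lasso_alpha, test_r = x$test_r,
         n_lasso_subset = x$n_lasso_subset)
}
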