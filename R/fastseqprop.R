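#' Differentiable motif count on a relaxed sequence
#'
#' Expected number of occurrences of a fixed motif under the per-position
#' base probabilities: `sum_p prod_j P(base_j at p + j)`. On a discrete
#' one-hot input this equals the exact overlapping motif count, and it is
#' differentiable in the probabilities — the design loss uses it to
#' penalize generated AUGs.
#'
#' @param relaxed `L x 4` matrix of per-position probabilities (columns
#'   A,C,G,T).
#' @param motif Motif string (default `"ATG"`).
#' @return A single number.
#' @examples
#' soft_motif_count(one_hot_encode("ATGATG"), "ATG")  # exactly 2
#' @export
soft_motif_count <- function(relaxed, motif = "ATG") {
  idx <- match(strsplit(normalize_dna(motif), "")[[1]], c("A", "C", "G", "T"))
  w <- length(idx)
  L <- nrow(relaxed)
  if (L < w) return(0)
  total <- 0
  for (p in seq_len(L - w + 1L)) {
    total <- total + prod(relaxed[cbind(p + seq_len(w) - 1L, idx)])
  }
  total
}

# gradient of soft_motif_count wrt the relaxed matrix
soft_motif_count_grad <- function(relaxed, motif = "ATG") {
  idx <- match(strsplit(normalize_dna(motif), "")[[1]], c("A", "C", "G", "T"))
  w <- length(idx)
  L <- nrow(relaxed)
  g <- matrix(0, L, 4L)
  if (L < w) return(g)
  for (p in seq_len(L - w + 1L)) {
    cells <- cbind(p + seq_len(w) - 1L, idx)
    vals <- relaxed[cells]
    for (j in seq_len(w)) {
      g[cells[j, 1], cells[j, 2]] <- g[cells[j, 1], cells[j, 2]] +
        prod(vals[-j])
    }
  }
  g
}

#' Soft penalty for a 5'-terminal TG dinucleotide
#'
#' `P(T at position 0) * P(G at position 1)`: 1 on discrete sequences
#' beginning `TG`, 0 otherwise. Used only for the fixed-end architecture,
#' whose constant region ends in `A`, so a variable region starting `TG`
#' would create an upstream AUG across the junction; random-end designs
#' disable it.
#'
#' @param relaxed `L x 4` probability matrix.
#' @param enabled Logical; when `FALSE` the term is identically 0.
#' @return A number in `[0, 1]`.
#' @export
startswith_ug_penalty <- function(relaxed, enabled = TRUE) {
  if (!enabled) return(0)
  unname(relaxed[1, 4] * relaxed[2, 3])  # P(T at 0) * P(G at 1)
}

startswith_ug_grad <- function(relaxed, enabled = TRUE) {
  g <- matrix(0, nrow(relaxed), 4L)
  if (!enabled) return(g)
  g[1, 4] <- relaxed[2, 3]
  g[2, 3] <- relaxed[1, 4]
  g
}

#' Composite design loss configuration
#'
#' The loss minimized by [fastseqprop_optimize()]: a fitness term (negative
#' predicted MRL, or `(predicted - target_mrl)^2` when a target is set)
#' plus sequence terms — `w_aug` times the AUG count, `w_ug` times the
#' initial-TG indicator, and `w_vae` times the VAE margin penalty.
#' Architecture defaults: fixed-end 50nt uses `margin = -30` with
#' `w_vae = 0.2` and the initial-TG penalty; random-end 25nt uses
#' `margin = -15.6` with `w_vae = 0.4` and no TG penalty.
#'
#' @param w_aug Weight of the AUG-count penalty (default 1).
#' @param w_ug Weight of the initial-TG penalty.
#' @param w_vae Weight of the VAE margin penalty (0 disables).
#' @param vae_margin Margin in nats.
#' @param target_mrl Optional target (switches fitness to squared error).
#' @param architecture Used to pick defaults; `"fixed_end_50"` enables the
#'   TG penalty and the -30 margin.
#' @return A `design_loss` list.
#' @export
design_loss <- function(w_aug = 1, w_ug = NULL, w_vae = 0, vae_margin = NULL,
                        target_mrl = NULL,
                        architecture = c("random_end_25", "fixed_end_50",
                                         "random_end_50")) {
  architecture <- match.arg(architecture)
  fixed <- architecture == "fixed_end_50"
  if (is.null(w_ug)) w_ug <- if (fixed) 1 else 0
  if (is.null(vae_margin)) vae_margin <- if (fixed) -30 else -15.6
  stopifnot(w_aug >= 0, w_ug >= 0, w_vae >= 0)
  structure(list(w_aug = w_aug, w_ug = w_ug, w_vae = w_vae,
                 vae_margin = vae_margin, target_mrl = target_mrl,
                 architecture = architecture),
            class = "design_loss")
}

#' Gradient-based single-sequence design (Fast SeqProp)
#'
#' Iteratively refines one sequence by gradient descent on trainable logits:
#' each iteration normalizes the logits per position, relaxes them through a
#' softmax, draws a discrete one-hot sample on the forward pass
#' (straight-through gradients), scores it with the frozen predictor, and
#' takes an Adam step on the composite [design_loss()]. The reported design
#' is the discrete sequence with the lowest total loss seen anywhere in the
#' trace (the stochastic forward sampling makes the final iterate noisy).
#' Recommended iteration counts: 20,000 without VAE regularization, 5,000
#' with it; small design problems converge far earlier.
#'
#' @param predictor Frozen predictor (`cnn_model`, `pwm_predictor`, ...).
#' @param loss A [design_loss()].
#' @param sequence_length Design length (nt).
#' @param n_iter Gradient updates; 0 returns the seeded random
#'   initialization.
#' @param lr Adam learning rate on the logits (default 0.01).
#' @param vae Trained [train_vae()] model (required when `loss$w_vae > 0`).
#' @param seed Seed for initialization and forward sampling.
#' @return A `fastseqprop_result` with `best_sequence`, `best_loss`,
#'   `best_predicted_mrl`, final `logits` and a per-iteration `trace`
#'   tibble (`loss`, `predicted_mrl`, `aug_count`, `best_loss`).
#' @export
fastseqprop_optimize <- function(predictor, loss = design_loss(),
                                 sequence_length = 25L, n_iter = 2000L,
                                 lr = 0.01, vae = NULL, seed = 1L) {
  if (loss$w_vae > 0 && is.null(vae)) {
    abort("loss$w_vae > 0 requires a trained `vae`")
  }
  set.seed(seed)
  L <- as.integer(sequence_length)
  logits <- matrix(rnorm(L * 4L, sd = 0.1), L, 4L)
  st <- adam1_init(logits)
  init_probs <- softmax_rows(logits - rowMeans(logits))
  init_seq <- one_hot_decode(sample_one_hot(init_probs))
  best <- list(loss = Inf, sequence = init_seq, mrl = NA_real_)
  if (n_iter == 0L) {
    best$mrl <- predict_mrl(predictor, init_seq)
    best$loss <- NA_real_
    return(structure(list(best_sequence = init_seq,
                          best_loss = NA_real_,
                          best_predicted_mrl = best$mrl, logits = logits,
                          trace = tibble()),
                     class = "fastseqprop_result"))
  }
  trace <- vector("list", n_iter)
  ug_enabled <- loss$w_ug > 0 && loss$architecture == "fixed_end_50"
  for (it in seq_len(n_iter)) {
    centered <- logits - rowMeans(logits)
    probs <- softmax_rows(centered)
    S <- sample_one_hot(probs)
    X <- array(S, c(1L, L, 4L))
    pred <- predict_relaxed(predictor, X)[1]
    if (is.null(loss$target_mrl)) {
      fit_loss <- -pred
      dpred <- -1
    } else {
      fit_loss <- (pred - loss$target_mrl)^2
      dpred <- 2 * (pred - loss$target_mrl)
    }
    # straight-through: gradient wrt the sample treated as gradient wrt P
    dP <- matrix(input_gradient(predictor, X, upstream = dpred), L, 4L)
    aug_discrete <- soft_motif_count(S)
    total <- fit_loss + loss$w_aug * aug_discrete
    if (loss$w_aug > 0) {
      dP <- dP + loss$w_aug * soft_motif_count_grad(probs)
    }
    if (ug_enabled) {
      total <- total + loss$w_ug * startswith_ug_penalty(S)
      dP <- dP + loss$w_ug * startswith_ug_grad(probs)
    }
    if (loss$w_vae > 0) {
      Xf <- matrix(as.numeric(t(probs)), 1L)
      eps <- matrix(rnorm(vae$spec$latent_dim), 1L)
      el <- vae_elbo_relaxed(vae, Xf, eps)
      pen <- margin_penalty(el$elbo, loss$vae_margin)
      total <- total + loss$w_vae * pen
      if (pen > 0) {
        dP <- dP + loss$w_vae * t(matrix(-el$delbo_dX[1, ], 4L, L))
      }
    }
    if (any(!is.finite(dP))) {
      abort(sprintf("non-finite design gradient at iteration %d", it))
    }
    # softmax (and per-position centering) backward
    dcentered <- probs * (dP - rowSums(dP * probs))
    dlogits <- dcentered - rowMeans(dcentered)
    upd <- adam1_step(logits, dlogits, st, lr = lr)
    logits <- upd$x
    st <- upd$state
    if (total < best$loss) {
      best <- list(loss = total, sequence = one_hot_decode(S), mrl = pred)
    }
    trace[[it]] <- tibble(iteration = it, loss = total, predicted_mrl = pred,
                          aug_count = aug_discrete, best_loss = best$loss)
  }
  structure(list(best_sequence = best$sequence, best_loss = best$loss,
                 best_predicted_mrl = best$mrl, logits = logits,
                 trace = bind_rows(trace), seed = seed),
            class = "fastseqprop_result")
}

#' @export
print.fastseqprop_result <- function(x, ...) {
  cat(sprintf(
    "<fastseqprop_result> best loss %.4f (predicted MRL %.3f)\n  %s\n",
    x$best_loss, x$best_predicted_mrl, x$best_sequence))
  invisible(x)
}

#' @export
tidy.fastseqprop_result <- function(x, ...) x$trace

#' @export
autoplot.fastseqprop_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_loss), colour = "red") +
    ggplot2::labs(y = "design loss (grey: per-iteration, red: best-so-far)") +
    ggplot2::theme_minimal()
}

#' Score designed sequences with an independent k-mer oracle
#'
#' Cross-validates designs against an independently trained linear model:
#' each design gets the oracle score and its percentile within a reference
#' pool of scored sequences, and a pass/flag call at a percentile
#' threshold.
#'
#' @param designs Character vector of sequences, or tibble with `sequence`.
#' @param oracle A [train_kmer_oracle()] model.
#' @param reference_pool Character vector / tibble of reference sequences
#'   (e.g. the MPRA library).
#' @param pass_percentile Designs at or above this percentile pass
#'   (default 50).
#' @return Tibble with `sequence`, `oracle_score`, `percentile`, `pass`.
#' @export
validate_with_oracle <- function(designs, oracle, reference_pool,
                                 pass_percentile = 50) {
  designs <- sequences_of(designs)
  if (length(designs) == 0L) {
    return(tibble(sequence = character(0), oracle_score = numeric(0),
                  percentile = numeric(0), pass = logical(0)))
  }
  pool <- sequences_of(reference_pool)
  if (length(pool) == 0L) abort("reference pool is empty")
  pool_scores <- predict_mrl(oracle, pool)
  scores <- predict_mrl(oracle, designs)
  pct <- vapply(scores, function(s) 100 * mean(pool_scores <= s), numeric(1))
  tibble(sequence = designs, oracle_score = scores, percentile = pct,
         pass = pct >= pass_percentile)
}
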