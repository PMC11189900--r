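#' Specification of an exploration-network sequence generator
#'
#' A generator network maps random seed inputs (plus a target-MRL input in
#' inverse-regression mode) to relaxed sequence matrices, and is trained
#' against a frozen predictor to emit diverse, high-fitness sequences:
#' the loss is `-fitness + diversity_weight * similarity + vae_weight *
#' margin_penalty`. In `"maximize"` mode fitness is the predicted MRL; in
#' `"inverse_regression"` mode fitness is `-(predicted MRL - target)^2` and
#' the target is supplied at generation time. Similarity is the mean
#' pairwise cosine similarity between the relaxed matrices of co-sampled
#' outputs; discrete outputs are drawn by straight-through sampling.
#'
#' @param predictor A frozen trained predictor ([train_cnn()] or
#'   [pwm_predictor()]).
#' @param sequence_length Output length (nt).
#' @param mode `"maximize"` or `"inverse_regression"`.
#' @param diversity_weight Weight of the pairwise-similarity penalty
#'   (default 5; 0 permits mode collapse).
#' @param vae_weight Weight of the VAE margin penalty (0 disables).
#' @param vae,vae_margin The [train_vae()] model and margin (nats) used when
#'   `vae_weight > 0`.
#' @param seed_input_dim Dimension of the random seed input (default 16).
#' @param hidden Hidden-layer width of the generator MLP.
#' @param target_range In inverse mode, the range targets are drawn from
#'   during training.
#' @return A `den_spec` list.
#' @export
den_spec <- function(predictor, sequence_length,
                     mode = c("maximize", "inverse_regression"),
                     diversity_weight = 5, vae_weight = 0, vae = NULL,
                     vae_margin = -30, seed_input_dim = 16L, hidden = 64L,
                     target_range = c(1.5, 7)) {
  mode <- match.arg(mode)
  stopifnot(diversity_weight >= 0, vae_weight >= 0)
  if (vae_weight > 0 && is.null(vae)) {
    abort("vae_weight > 0 requires a trained `vae`")
  }
  structure(list(predictor = predictor,
                 sequence_length = as.integer(sequence_length),
                 mode = mode, diversity_weight = diversity_weight,
                 vae_weight = vae_weight, vae = vae,
                 vae_margin = vae_margin,
                 seed_input_dim = as.integer(seed_input_dim),
                 hidden = as.integer(hidden),
                 target_range = target_range),
            class = "den_spec")
}

#' Train an exploration-network generator
#'
#' Stochastic gradient training of the generator MLP against the frozen
#' predictor. Each iteration samples a batch of seed inputs, relaxes them to
#' probability matrices, draws straight-through one-hot samples for the
#' fitness term, and backpropagates the composite loss into the generator
#' only.
#'
#' @param spec A [den_spec()].
#' @param n_iter Gradient updates (default 2000; inverse-regression
#'   conditioning benefits from more, e.g. 8000).
#' @param batch_size Co-sampled outputs per iteration (diversity is computed
#'   within this batch).
#' @param lr Adam learning rate (cut to 30% for the final quarter of
#'   training).
#' @param entropy_weight Weight of the sharpening term that drives the
#'   relaxed outputs toward one-hot vertices, ramped linearly over the
#'   first half of training (see Details).
#' @param seed Training seed.
#' @param verbose Print progress.
#' @details The fitness and penalty terms are evaluated on the relaxed
#'   probability matrices, which gives exact low-variance gradients; the
#'   entropy sharpening ramp then closes the gap between the relaxation and
#'   the discretely sampled outputs, so that generation-time samples score
#'   like the relaxations they are drawn from.
#' @return A `den_generator` with generator weights, the spec and a loss
#'   trace tibble.
#' @export
train_den <- function(spec, n_iter = 2000L, batch_size = 32L, lr = 3e-3,
                      entropy_weight = 0.5, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  L <- spec$sequence_length
  d_in <- spec$seed_input_dim +
    3L * (spec$mode == "inverse_regression")
  layers <- list(
    nn_init_dense(d_in, spec$hidden), list(type = "relu"),
    nn_init_dense(spec$hidden, spec$hidden), list(type = "relu"),
    nn_init_dense(spec$hidden, 4L * L))
  state <- adam_init(layers)
  trace <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    Z <- matrix(rnorm(batch_size * spec$seed_input_dim),
                batch_size, spec$seed_input_dim)
    targets <- NULL
    if (spec$mode == "inverse_regression") {
      targets <- runif(batch_size, spec$target_range[1], spec$target_range[2])
      Z <- cbind(Z, den_target_features(targets, spec$target_range))
    }
    w_ent <- entropy_weight * min(1, it / (n_iter / 2))
    lr_it <- lr * if (it > 0.75 * n_iter) 0.3 else 1
    step <- den_step(layers, state, Z, targets, spec, lr_it, w_ent)
    layers <- step$layers
    state <- step$state
    if (!is.finite(step$loss)) {
      abort(sprintf("generator training diverged at iteration %d", it))
    }
    trace[[it]] <- tibble(iteration = it, loss = step$loss,
                          fitness = step$fitness,
                          similarity = step$similarity,
                          vae_penalty = step$vae_penalty)
    if (verbose && it %% 100L == 0L) {
      cat(sprintf("iter %d  loss %.3f  fitness %.3f  sim %.3f\n",
                  it, step$loss, step$fitness, step$similarity))
    }
  }
  structure(list(spec = spec, layers = layers, trace = bind_rows(trace),
                 seed = seed),
            class = "den_generator")
}

# scaled polynomial embedding of the target input: conditioning on a bare
# scalar is weak, a cubic feature map is enough for the CNN-scale targets
den_target_features <- function(targets, target_range) {
  ts <- (targets - mean(target_range)) / (diff(target_range) / 2)
  cbind(ts, ts^2, ts^3)
}

# one training step; returns updated layers/state and loss components
den_step <- function(layers, state, Z, targets, spec, lr, w_ent = 0) {
  B <- nrow(Z)
  L <- spec$sequence_length
  fw <- nn_forward(layers, Z)
  logits <- array(fw$out, c(B, L, 4L))  # column-major: fills B, then L*4
  probs <- array(0, c(B, L, 4L))
  for (i in seq_len(B)) {
    probs[i, , ] <- softmax_rows(matrix(logits[i, , ], L, 4L))
  }
  pred <- predict_relaxed(spec$predictor, probs)
  if (spec$mode == "maximize") {
    fitness <- mean(pred)
    dpred <- rep(-1 / B, B)            # d(-fitness)/dpred
  } else {
    fitness <- -mean((pred - targets)^2)
    dpred <- 2 * (pred - targets) / B  # d(mean sq err)/dpred
  }
  dP <- input_gradient(spec$predictor, probs, upstream = dpred)
  if (w_ent > 0) {
    # mean per-position entropy, sharpening the relaxation toward vertices
    dP <- dP - w_ent * (log(probs + 1e-12) + 1) / (L * B)
  }
  # diversity: mean pairwise cosine similarity of flattened prob matrices
  sim <- 0
  if (spec$diversity_weight > 0 && B > 1L) {
    flat <- matrix(probs, B, L * 4L)
    nrm <- sqrt(rowSums(flat^2))
    U <- flat / nrm
    G <- tcrossprod(U)
    n_pairs <- B * (B - 1) / 2
    sim <- (sum(G) - B) / 2 / n_pairs
    # d sim/dU_i = sum_{j!=i} U_j / n_pairs; chain through the row
    # normalization: dflat_i = (v - (v.U_i) U_i)/||flat_i||
    dflat <- (matrix(colSums(U), B, L * 4L, byrow = TRUE) - U -
                (rowSums(G) - 1) * U) / nrm / n_pairs
    dP <- dP + spec$diversity_weight * array(dflat, c(B, L, 4L))
  }
  vae_pen <- 0
  if (spec$vae_weight > 0) {
    Xf <- matrix(0, B, 4L * L)
    for (i in seq_len(B)) Xf[i, ] <- as.numeric(t(matrix(probs[i, , ], L, 4L)))
    eps <- matrix(rnorm(B * spec$vae$spec$latent_dim), B,
                  spec$vae$spec$latent_dim)
    el <- vae_elbo_relaxed(spec$vae, Xf, eps)
    pen_active <- el$elbo < spec$vae_margin
    vae_pen <- mean(pmax(0, spec$vae_margin - el$elbo))
    dXf <- -el$delbo_dX * (pen_active / B)
    # back to (B, L, 4): rows of Xf are position-major blocks of 4
    for (i in seq_len(B)) {
      dP[i, , ] <- dP[i, , ] +
        spec$vae_weight * t(matrix(dXf[i, ], 4L, L))
    }
  }
  # softmax backward per sequence, then into the generator
  dlogits <- array(0, c(B, L, 4L))
  for (i in seq_len(B)) {
    pm <- matrix(probs[i, , ], L, 4L)
    dpm <- matrix(dP[i, , ], L, 4L)
    dlogits[i, , ] <- pm * (dpm - rowSums(dpm * pm))
  }
  bw <- nn_backward(layers, fw$caches, matrix(dlogits, B, L * 4L))
  upd <- adam_step(layers, bw$grads, state, lr = lr)
  list(layers = upd$layers, state = upd$state,
       loss = (if (spec$mode == "maximize") -fitness else -fitness) +
         spec$diversity_weight * sim + spec$vae_weight * vae_pen,
       fitness = fitness, similarity = sim, vae_penalty = vae_pen)
}

#' Generate sequences from a trained exploration network
#'
#' Draws `n` seed inputs, samples discrete sequences, scores them with the
#' frozen predictor, and returns them sorted by predicted MRL (descending).
#'
#' @param generator A [train_den()] result.
#' @param n Number of sequences (default 1024).
#' @param seed Sampling seed.
#' @param target Target MRL (inverse-regression generators only).
#' @return Tibble with `id`, `sequence`, `predicted_mrl`, sorted descending.
#' @export
den_generate <- function(generator, n = 1024L, seed = 1L, target = NULL) {
  spec <- generator$spec
  if (spec$mode == "inverse_regression" && is.null(target)) {
    abort("this generator requires a `target` MRL at generation time")
  }
  if (spec$mode == "maximize" && !is.null(target)) {
    abort("`target` is only accepted by inverse-regression generators")
  }
  set.seed(seed)
  L <- spec$sequence_length
  Z <- matrix(rnorm(n * spec$seed_input_dim), n, spec$seed_input_dim)
  if (!is.null(target)) {
    Z <- cbind(Z, den_target_features(rep(target, n), spec$target_range))
  }
  out <- nn_forward(generator$layers, Z)$out
  seqs <- character(n)
  S <- array(0, c(n, L, 4L))
  for (i in seq_len(n)) {
    pm <- softmax_rows(matrix(array(out[i, ], L * 4L), L, 4L))
    S[i, , ] <- sample_one_hot(pm)
    seqs[i] <- one_hot_decode(matrix(S[i, , ], L, 4L))
  }
  pred <- predict_relaxed(spec$predictor, S)
  tibble(id = sprintf("den_%04d", seq_len(n)), sequence = seqs,
         predicted_mrl = pred) |>
    arrange(desc(.data$predicted_mrl))
}

#' Seeded random pick from the top of a generated batch
#'
#' Mirrors the selection workflow for generated candidates: keep the top
#' `top_k` by predicted MRL and randomly choose `n_select` of them.
#'
#' @param generated A [den_generate()] tibble (already sorted).
#' @param n_select Number to select.
#' @param top_k Pool size (default 20).
#' @param seed Selection seed.
#' @return The selected rows.
#' @export
select_from_top <- function(generated, n_select = 5L, top_k = 20L,
                            seed = 1L) {
  pool <- head(generated, top_k)
  set.seed(seed)
  pool[sample.int(nrow(pool), min(n_select, nrow(pool))), , drop = FALSE]
}

#' @export
print.den_generator <- function(x, ...) {
  cat(sprintf(
    "<den_generator> %s mode, %dnt output; final loss %.3f (%d iterations)\n",
    x$spec$mode, x$spec$sequence_length,
    x$trace$loss[nrow(x$trace)], nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.den_generator <- function(x, ...) x$trace

#' @export
autoplot.den_generator <- function(object, ...) {
  h <- tidyr::pivot_longer(object$trace,
                           c("loss", "fitness", "similarity"),
                           names_to = "component", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}
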