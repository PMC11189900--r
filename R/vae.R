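#' Build the VAE training set
#'
#' Mirrors how the likelihood model's training data is assembled from an
#' MPRA table: filter by read coverage, take the top 10,000 sequences by
#' MRL (~top quartile at typical library sizes), and randomly draw disjoint
#' train and test sets from them. Default coverage: `> 2000` reads for the
#' fixed-end 50nt library, `> 500` for the random-end 25nt library.
#'
#' @param table MRL table with `sequence`, `mrl` and a read-depth column.
#' @param coverage Minimum read coverage (exclusive).
#' @param n_train,n_test Sizes of the random train/test selections.
#' @param top_pool Pool size ranked by MRL from which both sets are drawn
#'   (default 10000, truncated to the number of covered sequences).
#' @param seed Selection seed.
#' @return A `vae_trainset` list with tibbles `train` and `test`.
#' @export
build_vae_trainset <- function(table, coverage = 2000, n_train = 5000L,
                               n_test = 1000L, top_pool = 10000L, seed = 1L) {
  depth_col <- if ("reads" %in% names(table)) "reads" else "total_reads"
  covered <- table[table[[depth_col]] > coverage, , drop = FALSE]
  if (nrow(covered) < n_train + n_test) {
    abort(sprintf(
      "only %d sequences pass coverage > %g; need at least %d",
      nrow(covered), coverage, n_train + n_test))
  }
  pool <- covered |> arrange(desc(.data$mrl)) |>
    head(min(top_pool, nrow(covered)))
  if (nrow(pool) < n_train + n_test) {
    abort(sprintf("top pool of %d is smaller than n_train + n_test = %d",
                  nrow(pool), n_train + n_test))
  }
  set.seed(seed)
  idx <- sample.int(nrow(pool), n_train + n_test)
  structure(list(train = pool[idx[seq_len(n_train)], , drop = FALSE],
                 test = pool[idx[n_train + seq_len(n_test)], , drop = FALSE],
                 coverage = coverage, seed = seed),
            class = "vae_trainset")
}

#' Specification of the sequence VAE
#'
#' A variational autoencoder over one-hot 5'UTR sequences: dense encoder to
#' a diagonal-Gaussian latent, dense decoder to per-position categorical
#' logits. It learns the marginal distribution of its training sequences and
#' scores the likelihood of any new sequence, which the design algorithms
#' use as an in-distribution regularizer.
#'
#' @param sequence_length Sequence length (nt).
#' @param latent_dim Latent dimensionality (default 8).
#' @param hidden Width of the single encoder/decoder hidden layer.
#' @param kl_weight Weight of the KL term in the training objective.
#' @return A `vae_spec` list.
#' @export
vae_spec <- function(sequence_length, latent_dim = 8L, hidden = 64L,
                     kl_weight = 1) {
  stopifnot(latent_dim >= 1, kl_weight > 0)
  structure(list(sequence_length = as.integer(sequence_length),
                 latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), kl_weight = kl_weight),
            class = "vae_spec")
}

#' Train the sequence VAE
#'
#' Minimizes the negative evidence lower bound (categorical reconstruction
#' log-likelihood plus `kl_weight` times the KL divergence to the standard
#' normal prior) with Adam. All likelihood quantities are in nats.
#'
#' @param spec A [vae_spec()].
#' @param trainset A [build_vae_trainset()] result, or a tibble/character
#'   vector of sequences.
#' @param epochs,batch_size,lr Training configuration.
#' @param seed Seed for initialization, shuffling, and the reparameterized
#'   noise.
#' @param verbose Print per-epoch losses.
#' @return A `vae_model` with weights, `history`, reconstruction accuracy
#'   on the training set and, when a test set is available, its mean ELBO.
#' @export
train_vae <- function(spec, trainset, epochs = 60L, batch_size = 64L,
                      lr = 1e-3, seed = 1L, verbose = FALSE) {
  test <- NULL
  if (inherits(trainset, "vae_trainset")) {
    test <- trainset$test$sequence
    sequences <- trainset$train$sequence
  } else if (is.data.frame(trainset)) {
    sequences <- trainset$sequence
  } else {
    sequences <- as.character(trainset)
  }
  sequences <- normalize_dna(sequences)
  if (any(nchar(sequences) != spec$sequence_length)) {
    abort("all sequences must match spec$sequence_length")
  }
  set.seed(seed)
  L <- spec$sequence_length
  D <- 4L * L
  weights <- list(
    enc1 = nn_init_dense(D, spec$hidden),
    enc_mu = nn_init_dense(spec$hidden, spec$latent_dim),
    enc_lv = nn_init_dense(spec$hidden, spec$latent_dim),
    dec1 = nn_init_dense(spec$latent_dim, spec$hidden),
    dec_out = nn_init_dense(spec$hidden, D))
  state <- lapply(weights, function(w) {
    list(t = 0L, m = list(W = w$W * 0, b = w$b * 0),
         v = list(W = w$W * 0, b = w$b * 0))
  })
  X <- matrix(0, length(sequences), D)
  for (i in seq_along(sequences)) {
    X[i, ] <- as.numeric(t(one_hot_encode(sequences[i], L)))
  }
  # layout: position-major blocks of 4 (A,C,G,T) per position
  n <- nrow(X)
  history <- list()
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq.int(1L, n, batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      step <- vae_step(weights, X[idx, , drop = FALSE], spec, lr, state)
      if (!is.finite(step$loss)) {
        abort(sprintf("VAE training diverged at epoch %d", epoch))
      }
      weights <- step$weights
      state <- step$state
      ep_loss <- ep_loss + step$loss * length(idx)
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = ep_loss / n)
    if (verbose) cat(sprintf("epoch %d  -ELBO %.3f\n", epoch, ep_loss / n))
  }
  model <- structure(list(spec = spec, weights = weights,
                          history = bind_rows(history), seed = seed),
                     class = "vae_model")
  model$train_recon_accuracy <- vae_reconstruction_accuracy(model, sequences)
  if (!is.null(test)) {
    model$test_mean_elbo <- mean(estimate_log_likelihood(
      model, test, seed = seed)$log_p_estimate)
  }
  model
}

# one Adam step on a minibatch; returns loss (mean -ELBO) and new weights
vae_step <- function(weights, Xb, spec, lr, state) {
  B <- nrow(Xb)
  fw <- vae_forward(weights, Xb, eps = matrix(rnorm(B * spec$latent_dim),
                                              B, spec$latent_dim))
  loss <- mean(-fw$recon + spec$kl_weight * fw$kl)
  # gradients of mean over batch
  grads <- vae_backward(weights, fw, Xb, spec, target = Xb)
  for (nm in names(weights)) {
    st <- state[[nm]]
    st$t <- st$t + 1L
    for (p in c("W", "b")) {
      g <- grads[[nm]][[p]]
      st$m[[p]] <- 0.9 * st$m[[p]] + 0.1 * g
      st$v[[p]] <- 0.999 * st$v[[p]] + 0.001 * g^2
      mhat <- st$m[[p]] / (1 - 0.9^st$t)
      vhat <- st$v[[p]] / (1 - 0.999^st$t)
      weights[[nm]][[p]] <- weights[[nm]][[p]] -
        lr * mhat / (sqrt(vhat) + 1e-8)
    }
    state[[nm]] <- st
  }
  list(weights = weights, state = state, loss = loss)
}

# Forward pass; Xb rows are flattened (position-major) relaxed/one-hot
# sequences. Returns everything needed for the backward pass.
vae_forward <- function(weights, Xb, eps) {
  B <- nrow(Xb)
  h1_pre <- Xb %*% weights$enc1$W + rep(weights$enc1$b, each = B)
  h1 <- pmax(h1_pre, 0)
  mu <- h1 %*% weights$enc_mu$W + rep(weights$enc_mu$b, each = B)
  lv <- h1 %*% weights$enc_lv$W + rep(weights$enc_lv$b, each = B)
  lv <- pmin(pmax(lv, -10), 10)
  z <- mu + exp(lv / 2) * eps
  h2_pre <- z %*% weights$dec1$W + rep(weights$dec1$b, each = B)
  h2 <- pmax(h2_pre, 0)
  logits <- h2 %*% weights$dec_out$W + rep(weights$dec_out$b, each = B)
  L <- ncol(Xb) %/% 4L
  # row-wise per-position log-softmax
  lp <- matrix(0, B, ncol(Xb))
  probs <- matrix(0, B, ncol(Xb))
  for (p in seq_len(L)) {
    cols <- (p - 1L) * 4L + 1:4
    zb <- logits[, cols, drop = FALSE]
    zb <- zb - apply(zb, 1, max)
    lse <- log(rowSums(exp(zb)))
    lp[, cols] <- zb - lse
    probs[, cols] <- exp(zb - lse)
  }
  recon <- rowSums(Xb * lp)
  kl <- 0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
  list(h1_pre = h1_pre, h1 = h1, mu = mu, lv = lv, eps = eps, z = z,
       h2_pre = h2_pre, h2 = h2, logits = logits, log_probs = lp,
       probs = probs, recon = recon, kl = kl)
}

# Backward pass for loss = mean(-recon + kl_weight * kl); also returns the
# gradient with respect to the (relaxed) input rows, used by the design
# regularizer.
vae_backward <- function(weights, fw, Xb, spec, target) {
  B <- nrow(Xb)
  # d(-recon)/dlogits = (probs * rowsum(target per position) - target)/B
  dlogits <- (fw$probs * rep_cols_sum4(target) - target) / B
  g <- list()
  g$dec_out <- list(W = crossprod(fw$h2, dlogits), b = colSums(dlogits))
  dh2 <- tcrossprod(dlogits, weights$dec_out$W) * (fw$h2_pre > 0)
  g$dec1 <- list(W = crossprod(fw$z, dh2), b = colSums(dh2))
  dz <- tcrossprod(dh2, weights$dec1$W)
  # KL gradients
  dmu <- dz + spec$kl_weight * fw$mu / B
  dlv <- dz * fw$eps * exp(fw$lv / 2) / 2 +
    spec$kl_weight * 0.5 * (exp(fw$lv) - 1) / B
  g$enc_mu <- list(W = crossprod(fw$h1, dmu), b = colSums(dmu))
  g$enc_lv <- list(W = crossprod(fw$h1, dlv), b = colSums(dlv))
  dh1 <- (tcrossprod(dmu, weights$enc_mu$W) +
            tcrossprod(dlv, weights$enc_lv$W)) * (fw$h1_pre > 0)
  g$enc1 <- list(W = crossprod(Xb, dh1), b = colSums(dh1))
  g$dX <- tcrossprod(dh1, weights$enc1$W) - fw$log_probs / B
  g
}

# For each position block of 4 columns, the row sums of x over that block,
# broadcast back to the 4 columns (so one-hot inputs give 1 everywhere).
rep_cols_sum4 <- function(x) {
  L <- ncol(x) %/% 4L
  out <- matrix(0, nrow(x), ncol(x))
  for (p in seq_len(L)) {
    cols <- (p - 1L) * 4L + 1:4
    out[, cols] <- rowSums(x[, cols, drop = FALSE])
  }
  out
}

#' Estimate sequence log-likelihood under a trained VAE
#'
#' Two estimators, both in nats: `"elbo"`, the single-sample evidence lower
#' bound (one reparameterized reconstruction sample, analytic KL), and
#' `"importance_weighted"`, the K-sample importance-weighted bound
#' `log mean_k p(x | z_k) p(z_k) / q(z_k | x)`, which is tighter on average
#' and approaches the true log-likelihood as K grows. Deterministic given
#' `seed`.
#'
#' @param vae A [train_vae()] model.
#' @param sequences Character vector of sequences.
#' @param estimator `"elbo"` or `"importance_weighted"`.
#' @param n_samples K for the importance-weighted estimator.
#' @param seed Seed for the posterior samples.
#' @return Tibble with `sequence`, `log_p_estimate`, `estimator`,
#'   `n_samples`.
#' @export
estimate_log_likelihood <- function(vae, sequences, estimator = c(
                                      "elbo", "importance_weighted"),
                                    n_samples = 1L, seed = 1L) {
  estimator <- match.arg(estimator)
  sequences <- normalize_dna(sequences)
  L <- vae$spec$sequence_length
  if (any(nchar(sequences) != L)) abort("sequence length mismatch with VAE")
  set.seed(seed)
  X <- matrix(0, length(sequences), 4L * L)
  for (i in seq_along(sequences)) {
    X[i, ] <- as.numeric(t(one_hot_encode(sequences[i], L)))
  }
  K <- if (estimator == "elbo") 1L else as.integer(n_samples)
  d <- vae$spec$latent_dim
  n <- nrow(X)
  logw <- matrix(0, n, K)
  for (k in seq_len(K)) {
    fw <- vae_forward(vae$weights, X, eps = matrix(rnorm(n * d), n, d))
    if (estimator == "elbo") {
      logw[, k] <- fw$recon - fw$kl
    } else {
      log_prior <- -0.5 * rowSums(fw$z^2) - 0.5 * d * log(2 * pi)
      log_q <- -0.5 * rowSums((fw$z - fw$mu)^2 / exp(fw$lv)) -
        0.5 * rowSums(fw$lv) - 0.5 * d * log(2 * pi)
      logw[, k] <- fw$recon + log_prior - log_q
    }
  }
  est <- if (K == 1L) logw[, 1] else apply(logw, 1, logsumexp) - log(K)
  tibble(sequence = sequences, log_p_estimate = est,
         estimator = estimator, n_samples = K)
}

# ELBO (and its input gradient) of relaxed probability rows; eps fixed.
vae_elbo_relaxed <- function(vae, Xb, eps) {
  fw <- vae_forward(vae$weights, Xb, eps)
  g <- vae_backward(vae$weights, fw, Xb, vae$spec, target = Xb)
  # vae_backward returns gradient of mean(-elbo) wrt input (kl_weight = 1
  # in the spec gives the true ELBO); flip sign and scale by B
  list(elbo = fw$recon - fw$kl, delbo_dX = -g$dX * nrow(Xb))
}

vae_reconstruction_accuracy <- function(vae, sequences) {
  L <- vae$spec$sequence_length
  X <- matrix(0, length(sequences), 4L * L)
  for (i in seq_along(sequences)) {
    X[i, ] <- as.numeric(t(one_hot_encode(sequences[i], L)))
  }
  fw <- vae_forward(vae$weights, X,
                    eps = matrix(0, nrow(X), vae$spec$latent_dim))
  correct <- 0L
  for (p in seq_len(L)) {
    cols <- (p - 1L) * 4L + 1:4
    correct <- correct +
      sum(max.col(fw$probs[, cols, drop = FALSE], ties.method = "first") ==
            max.col(X[, cols, drop = FALSE], ties.method = "first"))
  }
  correct / (length(sequences) * L)
}

#' Margin penalty on an estimated log-likelihood
#'
#' `max(0, margin - log_p)`: zero when the sequence is at least as likely as
#' the margin, growing linearly (slope -1 in `log_p`) below it. The margins
#' used for design are in nats: -30 for the fixed-end 50nt architecture and
#' -15.6 for the random-end 25nt architecture.
#'
#' @param log_p Estimated log-likelihood(s), nats.
#' @param margin Margin, nats.
#' @return Non-negative penalty, vectorized over `log_p`.
#' @export
margin_penalty <- function(log_p, margin = -30) {
  pmax(0, margin - log_p)
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf(
    "<vae_model> %dnt sequences, latent %d; train recon acc %.3f\n",
    x$spec$sequence_length, x$spec$latent_dim,
    x$train_recon_accuracy %||% NA_real_))
  invisible(x)
}

#' @export
tidy.vae_model <- function(x, ...) x$history

#' @export
glance.vae_model <- function(x, ...) {
  tibble(final_loss = x$history$loss[nrow(x$history)],
         train_recon_accuracy = x$train_recon_accuracy %||% NA_real_,
         test_mean_elbo = x$test_mean_elbo %||% NA_real_,
         latent_dim = x$spec$latent_dim)
}
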