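# Minimal dense/convolutional network engine.
#
# All models in this package (the convolutional MRL predictor, the sequence
# VAE, the exploration-network generator, and the Fast SeqProp optimizer)
# share this compact reference implementation of forward/backward passes and
# Adam updates, written with base matrix algebra so that training is
# single-threaded BLAS and bitwise reproducible given a seed. Shapes follow
# the sequence convention: batches are (B, L, 4) arrays until a `flatten`
# layer, matrices afterwards.
#
# Layers are plain lists: list(type = "conv", W, b, k), list(type = "relu"),
# list(type = "pool"), list(type = "dropout", rate), list(type = "flatten"),
# list(type = "dense", W, b). Convolutions are length-preserving ("same"
# zero padding); pooling is max, size and stride 2.

nn_init_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

nn_init_conv <- function(c_in, filters, k) {
  list(type = "conv",
       W = matrix(rnorm(k * c_in * filters, sd = sqrt(2 / (k * c_in))),
                  k * c_in, filters),
       b = numeric(filters), k = k)
}

# (B, L+k-1, C) zero-padded copy of X
nn_pad <- function(X, k) {
  d <- dim(X)
  pad_l <- (k - 1L) %/% 2L
  Xp <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  Xp[, pad_l + seq_len(d[2]), ] <- X
  Xp
}

# (B*L) x (k*C) patch matrix; row index runs batch-fastest, then position
nn_im2col <- function(Xp, L, k) {
  B <- dim(Xp)[1]; C <- dim(Xp)[3]
  out <- matrix(0, B * L, k * C)
  for (j in seq_len(k)) {
    out[, ((j - 1L) * C + 1L):(j * C)] <-
      matrix(Xp[, j:(j + L - 1L), , drop = FALSE], B * L, C)
  }
  out
}

nn_conv_forward <- function(layer, X) {
  d <- dim(X); B <- d[1]; L <- d[2]
  col <- nn_im2col(nn_pad(X, layer$k), L, layer$k)
  Y <- col %*% layer$W
  Y <- Y + rep(layer$b, each = B * L)
  list(out = array(Y, c(B, L, ncol(layer$W))),
       cache = list(col = col, B = B, L = L, C = d[3]))
}

nn_conv_backward <- function(layer, cache, dY) {
  B <- cache$B; L <- cache$L; C <- cache$C; k <- layer$k
  dY2 <- matrix(dY, B * L, ncol(layer$W))
  dW <- crossprod(cache$col, dY2)
  db <- colSums(dY2)
  dcol <- tcrossprod(dY2, layer$W)
  dXp <- array(0, c(B, L + k - 1L, C))
  for (j in seq_len(k)) {
    dXp[, j:(j + L - 1L), ] <- dXp[, j:(j + L - 1L), , drop = FALSE] +
      array(dcol[, ((j - 1L) * C + 1L):(j * C)], c(B, L, C))
  }
  pad_l <- (k - 1L) %/% 2L
  list(dX = dXp[, pad_l + seq_len(L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

nn_pool_forward <- function(X) {
  d <- dim(X); Lout <- d[2] %/% 2L
  A <- X[, seq.int(1L, 2L * Lout, 2L), , drop = FALSE]
  B2 <- X[, seq.int(2L, 2L * Lout, 2L), , drop = FALSE]
  mask <- A >= B2
  list(out = pmax(A, B2), cache = list(mask = mask, L = d[2]))
}

nn_pool_backward <- function(cache, dY) {
  d <- dim(dY); Lout <- d[2]
  dX <- array(0, c(d[1], cache$L, d[3]))
  dX[, seq.int(1L, 2L * Lout, 2L), ] <- dY * cache$mask
  dX[, seq.int(2L, 2L * Lout, 2L), ] <- dY * !cache$mask
  dX
}

nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      fw <- nn_conv_forward(ly, X); X <- fw$out; caches[[i]] <- fw$cache
    } else if (ly$type == "relu") {
      caches[[i]] <- X > 0
      X <- X * caches[[i]]
    } else if (ly$type == "pool") {
      fw <- nn_pool_forward(X); X <- fw$out; caches[[i]] <- fw$cache
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- array(runif(length(X)) >= ly$rate, dim(X) %||% length(X)) /
          (1 - ly$rate)
        caches[[i]] <- mask
        X <- X * mask
      }
    } else if (ly$type == "flatten") {
      d <- dim(X)
      caches[[i]] <- d
      X <- matrix(X, d[1], prod(d[-1]))
    } else if (ly$type == "dense") {
      caches[[i]] <- X
      X <- X %*% ly$W + rep(ly$b, each = nrow(X))
    } else {
      abort(sprintf("unknown layer type '%s'", ly$type))
    }
  }
  list(out = X, caches = caches)
}

# Returns list(grads = per-layer list, dX = gradient wrt the input array)
nn_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      bw <- nn_conv_backward(ly, caches[[i]], dY)
      dY <- bw$dX; grads[[i]] <- bw$grads
    } else if (ly$type == "relu") {
      dY <- dY * caches[[i]]
    } else if (ly$type == "pool") {
      dY <- nn_pool_backward(caches[[i]], dY)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) dY <- dY * caches[[i]]
    } else if (ly$type == "flatten") {
      dY <- array(dY, caches[[i]])
    } else if (ly$type == "dense") {
      X <- caches[[i]]
      grads[[i]] <- list(W = crossprod(X, dY), b = colSums(dY))
      dY <- tcrossprod(dY, ly$W)
    }
  }
  list(grads = grads, dX = dY)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  state <- list(t = 0L, m = vector("list", length(layers)),
                v = vector("list", length(layers)))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (!is.null(ly$W)) {
      state$m[[i]] <- list(W = ly$W * 0, b = ly$b * 0)
      state$v[[i]] <- list(W = ly$W * 0, b = ly$b * 0)
    }
  }
  state
}

adam_step <- function(layers, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in c("W", "b")) {
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g[[p]]
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g[[p]]^2
      mhat <- state$m[[i]][[p]] / corr1
      vhat <- state$v[[i]][[p]] / corr2
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

# Generic single-tensor Adam (used for Fast SeqProp logits).
adam1_init <- function(x) list(t = 0L, m = x * 0, v = x * 0)

adam1_step <- function(x, g, state, lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# --- small helpers ---------------------------------------------------------

# row-wise softmax of an L x 4 matrix (or (B, L, 4) array along last dim)
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Sample a one-hot matrix from row-wise probabilities (straight-through
# forward pass); returns L x 4 0/1 matrix.
sample_one_hot <- function(probs) {
  L <- nrow(probs)
  u <- runif(L)
  cum <- probs %*% upper.tri(matrix(1, 4, 4), diag = TRUE) * 1
  idx <- 5L - as.integer(rowSums(u <= cum))
  # guard against numerical drift in the cumulative sums
  idx[idx < 1L] <- 1L; idx[idx > 4L] <- 4L
  out <- matrix(0, L, 4L)
  out[cbind(seq_len(L), idx)] <- 1
  out
}
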