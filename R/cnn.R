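#' Specification of the convolutional MRL predictor
#'
#' Describes the VGG-style architecture family used for MRL prediction from
#' one-hot encoded 5'UTRs: `n_blocks` convolutional blocks, each consisting
#' of two length-preserving convolutional layers, one max-pooling layer with
#' size and stride 2, and one dropout layer; followed by a fully connected
#' dense layer and a final linear node. All activations except the final
#' node are ReLU, and the number of filters doubles from block to block.
#'
#' @param input_length One-hot input width (nt).
#' @param n_blocks Number of convolutional blocks (1-5).
#' @param base_filters Filters in the first block (16-128); block `b` has
#'   `base_filters * 2^(b-1)`.
#' @param kernel_size Convolution kernel size (2-7).
#' @param conv_dropout,dense_dropout Dropout rates (0-0.5).
#' @param dense_units Units in the dense layer (10-100).
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(input_length = 25L, n_blocks = 2L, base_filters = 16L,
                     kernel_size = 5L, conv_dropout = 0.1,
                     dense_units = 50L, dense_dropout = 0.2) {
  stopifnot(n_blocks >= 1, n_blocks <= 5,
            kernel_size >= 2, kernel_size <= 7,
            base_filters >= 16, base_filters <= 128,
            conv_dropout >= 0, conv_dropout <= 0.5,
            dense_dropout >= 0, dense_dropout <= 0.5,
            dense_units >= 10, dense_units <= 100)
  if (input_length %/% 2^n_blocks < 1) {
    abort("too many pooling steps for this input length")
  }
  structure(list(input_length = as.integer(input_length),
                 n_blocks = as.integer(n_blocks),
                 base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size),
                 conv_dropout = conv_dropout,
                 dense_units = as.integer(dense_units),
                 dense_dropout = dense_dropout),
            class = "cnn_spec")
}

# Instantiate the layer list for a cnn_spec (uses the current RNG state).
cnn_build_layers <- function(spec) {
  layers <- list()
  c_in <- 4L
  L <- spec$input_length
  for (b in seq_len(spec$n_blocks)) {
    f <- spec$base_filters * 2L^(b - 1L)
    layers <- c(layers, list(
      nn_init_conv(c_in, f, spec$kernel_size), list(type = "relu"),
      nn_init_conv(f, f, spec$kernel_size), list(type = "relu"),
      list(type = "pool"),
      list(type = "dropout", rate = spec$conv_dropout)))
    c_in <- f
    L <- L %/% 2L
  }
  layers <- c(layers, list(
    list(type = "flatten"),
    nn_init_dense(L * c_in, spec$dense_units), list(type = "relu"),
    list(type = "dropout", rate = spec$dense_dropout),
    nn_init_dense(spec$dense_units, 1L)))
  layers
}

#' Train the convolutional MRL predictor
#'
#' Minimizes mean squared error with Adam and early stopping on validation
#' loss: training stops when the validation loss has not improved for
#' `patience` consecutive epochs, and the parameters from the best epoch are
#' kept. Training is deterministic given `seed` (single-threaded BLAS
#' assumed).
#'
#' @param spec A [cnn_spec()].
#' @param train A tibble with `sequence` and `mrl` columns (training set),
#'   or a [make_split()] result (in which case `validation` is taken from
#'   it).
#' @param validation Validation tibble (`sequence`, `mrl`).
#' @param max_epochs,patience,batch_size,lr Training configuration.
#' @param weight_decay Decoupled L2 weight decay per update (default 0).
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return A `cnn_model` with elements `spec`, `layers` and `history`
#'   (tibble of per-epoch train/validation loss).
#' @export
train_cnn <- function(spec, train, validation = NULL, max_epochs = 30L,
                      patience = 5L, batch_size = 128L, lr = 1e-3,
                      weight_decay = 0, seed = 1L, verbose = FALSE) {
  if (inherits(train, "mrl_split")) {
    validation <- train$validation
    train <- train$train
  }
  if (is.null(validation)) abort("a validation set is required")
  set.seed(seed)
  layers <- cnn_build_layers(spec)
  state <- adam_init(layers)
  Xtr <- one_hot_encode_batch(train$sequence, spec$input_length)
  ytr <- train$mrl
  Xva <- one_hot_encode_batch(validation$sequence, spec$input_length)
  yva <- validation$mrl
  n <- length(ytr)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  history <- list()
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    for (start in seq.int(1L, n, batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- Xtr[idx, , , drop = FALSE]
      fw <- nn_forward(layers, Xb, training = TRUE)
      resid <- fw$out[, 1] - ytr[idx]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        abort(sprintf("training diverged (non-finite loss at epoch %d)",
                      epoch))
      }
      tr_loss <- tr_loss + loss * length(idx)
      dY <- matrix(2 * resid / length(idx), ncol = 1L)
      bw <- nn_backward(layers, fw$caches, dY)
      upd <- adam_step(layers, bw$grads, state, lr = lr)
      layers <- upd$layers
      if (weight_decay > 0) {
        for (li in seq_along(layers)) {
          if (!is.null(layers[[li]]$W)) {
            layers[[li]]$W <- layers[[li]]$W * (1 - lr * weight_decay)
          }
        }
      }
      state <- upd$state
    }
    val_pred <- nn_predict(layers, Xva)
    val_loss <- mean((val_pred - yva)^2)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss / n,
                               val_loss = val_loss)
    if (verbose) {
      cat(sprintf("epoch %d  train %.4f  val %.4f\n", epoch, tr_loss / n,
                  val_loss))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, layers = layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(spec = spec, layers = best$layers,
                 history = bind_rows(history), best_epoch = best$epoch,
                 val_loss = best$loss, seed = seed),
            class = "cnn_model")
}

# Batched deterministic forward pass (no dropout).
nn_predict <- function(layers, X, batch = 1024L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq.int(1L, n, batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx] <- nn_forward(layers, X[idx, , , drop = FALSE])$out[, 1]
  }
  out
}

#' Predict MRL for 5'UTR sequences
#'
#' Deterministic, vectorized, order-preserving prediction. Sequences shorter
#' than the model input are zero-padded on the left.
#'
#' @param predictor A trained predictor (`cnn_model`, `pwm_predictor`,
#'   `positional_3mer_model`, or `kmer_oracle`).
#' @param sequences Character vector of sequences, or a tibble/`utr_library`
#'   with a `sequence` column.
#' @return Numeric vector of predicted MRLs.
#' @export
predict_mrl <- function(predictor, sequences) {
  UseMethod("predict_mrl")
}

#' @export
predict_mrl.cnn_model <- function(predictor, sequences) {
  sequences <- sequences_of(sequences)
  X <- one_hot_encode_batch(sequences, predictor$spec$input_length)
  nn_predict(predictor$layers, X)
}

sequences_of <- function(x) {
  if (is.data.frame(x)) x$sequence else as.character(x)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> input %dnt, %d blocks (%d base filters, kernel %d); best epoch %d (val MSE %.4f)\n",
    x$spec$input_length, x$spec$n_blocks, x$spec$base_filters,
    x$spec$kernel_size, x$best_epoch, x$val_loss))
  invisible(x)
}

#' @export
tidy.cnn_model <- function(x, ...) x$history

#' @export
glance.cnn_model <- function(x, ...) {
  tibble(best_epoch = x$best_epoch, val_mse = x$val_loss,
         n_parameters = sum(vapply(x$layers, function(l) {
           length(l$W) + length(l$b)
         }, numeric(1))),
         n_blocks = x$spec$n_blocks, input_length = x$spec$input_length)
}

#' @export
autoplot.cnn_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(y = "MSE loss") +
    ggplot2::theme_minimal()
}

# --- differentiable predictor interface -----------------------------------
# Design algorithms need a score and its gradient with respect to a relaxed
# (probability) sequence matrix.

# score a batch given a (B, L, 4) array of one-hot / relaxed inputs
predict_relaxed <- function(predictor, X) UseMethod("predict_relaxed")

# gradient of sum(score * upstream) wrt X; upstream is length-B
input_gradient <- function(predictor, X, upstream = 1) {
  UseMethod("input_gradient")
}

#' @export
predict_relaxed.cnn_model <- function(predictor, X) {
  nn_forward(predictor$layers, X)$out[, 1]
}

#' @export
input_gradient.cnn_model <- function(predictor, X, upstream = 1) {
  fw <- nn_forward(predictor$layers, X)
  dY <- matrix(rep_len(upstream, dim(X)[1]), ncol = 1L)
  nn_backward(predictor$layers, fw$caches, dY)$dX
}

#' Position-weight-matrix toy predictor
#'
#' A linear, additive per-position scorer `score = sum_p PWM[p, base_p]`
#' plus an intercept. Its unique optimum is the per-position argmax
#' sequence, which makes it the analytic test bed for the design
#' algorithms.
#'
#' @param pwm `L x 4` numeric matrix (columns A,C,G,T).
#' @param intercept Added constant.
#' @return A `pwm_predictor`.
#' @export
pwm_predictor <- function(pwm, intercept = 0) {
  stopifnot(ncol(pwm) == 4L)
  colnames(pwm) <- c("A", "C", "G", "T")
  structure(list(pwm = pwm, intercept = intercept,
                 input_length = nrow(pwm)),
            class = "pwm_predictor")
}

#' @export
predict_mrl.pwm_predictor <- function(predictor, sequences) {
  sequences <- sequences_of(sequences)
  X <- one_hot_encode_batch(sequences, predictor$input_length)
  predict_relaxed(predictor, X)
}

#' @export
predict_relaxed.pwm_predictor <- function(predictor, X) {
  B <- dim(X)[1]
  flat <- matrix(X, B, length(predictor$pwm))
  as.numeric(flat %*% as.numeric(predictor$pwm)) + predictor$intercept
}

#' @export
input_gradient.pwm_predictor <- function(predictor, X, upstream = 1) {
  B <- dim(X)[1]
  up <- rep_len(upstream, B)
  g <- array(0, dim(X))
  for (i in seq_len(B)) g[i, , ] <- up[i] * predictor$pwm
  g
}
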