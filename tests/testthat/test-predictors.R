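test_that("depth-ranked splits are deterministic with stable tie-breaks", {
  tab <- tibble::tibble(variant_id = sprintf("v%02d", 1:10),
                        reads = c(5, 9, 9, 7, 3, 8, 2, 6, 4, 1),
                        sequence = "ACGTACGT", mrl = 1:10)
  sp <- make_split(tab, k_test = 2, k_val = 2)
  expect_identical(nrow(sp$train), 6L)
  # depth 9 tie between v02 and v03 broken by id
  expect_identical(sp$test$variant_id, c("v02", "v03"))
  expect_identical(sp$validation$variant_id, c("v06", "v04"))
  expect_error(make_split(tab, 5, 5), "need more")

  # matches a brute-force sort oracle on a larger table
  set.seed(31)
  big <- tibble::tibble(variant_id = sprintf("v%05d", 1:5000),
                        reads = sample(1:500, 5000, TRUE),
                        sequence = "ACGT", mrl = rnorm(5000))
  sp2 <- make_split(big, 100, 100)
  ord <- big[order(-big$reads, big$variant_id), ]
  expect_identical(sp2$test$variant_id, ord$variant_id[1:100])
  expect_identical(sp2$train$variant_id, ord$variant_id[201:5000])
})

test_that("evaluate_r2 is the squared Pearson correlation", {
  x <- rnorm(50)
  expect_equal(evaluate_r2(x, x), 1.0)
  expect_equal(evaluate_r2(-x, x), 1.0)
  set.seed(32)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    want <- (sum((a - mean(a)) * (b - mean(b))) /
               sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
    expect_equal(evaluate_r2(a, b), want, tolerance = 1e-12)
  }
  expect_error(evaluate_r2(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(evaluate_r2(1:3, 1:4), "equal-length")
})

test_that("the convolutional architecture family matches its description", {
  spec <- cnn_spec(input_length = 25, n_blocks = 2, base_filters = 16,
                   kernel_size = 5)
  layers <- utrforge:::cnn_build_layers(spec)
  types <- vapply(layers, function(l) l$type, character(1))
  expect_identical(types,
                   c("conv", "relu", "conv", "relu", "pool", "dropout",
                     "conv", "relu", "conv", "relu", "pool", "dropout",
                     "flatten", "dense", "relu", "dropout", "dense"))
  # filters double between blocks; kernel x channels rows in W
  expect_identical(dim(layers[[1]]$W), c(5L * 4L, 16L))
  expect_identical(dim(layers[[3]]$W), c(5L * 16L, 16L))
  expect_identical(dim(layers[[7]]$W), c(5L * 16L, 32L))
  expect_identical(dim(layers[[9]]$W), c(5L * 32L, 32L))
  # after two stride-2 pools: 25 -> 12 -> 6 positions, 32 channels
  expect_identical(dim(layers[[14]]$W), c(6L * 32L, 50L))
  expect_identical(dim(layers[[17]]$W), c(50L, 1L))
  expect_error(cnn_spec(base_filters = 4), "base_filters")
  expect_error(cnn_spec(kernel_size = 9), "kernel_size")
})

test_that("CNN training fits a constant target and is seed-reproducible", {
  tab <- planted_table(1200, seed = 33)
  tab$mrl <- 4.2
  sp <- list(train = tab[1:1000, ], validation = tab[1001:1200, ])
  m <- train_cnn(cnn_spec(n_blocks = 1, dense_units = 10,
                          conv_dropout = 0, dense_dropout = 0),
                 sp$train, sp$validation, max_epochs = 40, patience = 40,
                 batch_size = 128, lr = 3e-3, weight_decay = 10, seed = 7)
  expect_lt(m$val_loss, 1e-2)
  expect_equal(predict_mrl(m, tab$sequence[1:5]), rep(4.2, 5),
               tolerance = 0.05)

  m2 <- train_cnn(cnn_spec(n_blocks = 1, dense_units = 10),
                  sp$train, sp$validation, max_epochs = 3, patience = 3,
                  batch_size = 64, seed = 9)
  m3 <- train_cnn(cnn_spec(n_blocks = 1, dense_units = 10),
                  sp$train, sp$validation, max_epochs = 3, patience = 3,
                  batch_size = 64, seed = 9)
  expect_identical(m2$history, m3$history)

  # prediction is order-preserving and batch-size independent
  p_all <- predict_mrl(m, tab$sequence[1:10])
  expect_equal(p_all[10:1], predict_mrl(m, tab$sequence[10:1]))
  expect_equal(p_all[3], predict_mrl(m, tab$sequence[3]))
})

test_that("positional 3-mer regression recovers a planted linear model", {
  # plant weights inside the identifiable space of the indicator design
  # (offset one-hot blocks and overlapping 3-mers are collinear) by
  # projecting a random vector through a noiseless fit, then test recovery
  # on fresh noisy data
  lib0 <- generate_library(6000, seed = 34)
  w0 <- rnorm(23 * 64, sd = 0.15)
  X0 <- utrforge:::positional_3mer_matrix(lib0$sequence)
  proj <- train_positional_3mer(
    tibble::tibble(sequence = lib0$sequence,
                   mrl = as.numeric(X0 %*% w0) + 3))
  w_pl <- proj$coef

  lib <- generate_library(6000, seed = 35)
  X <- utrforge:::positional_3mer_matrix(lib$sequence)
  set.seed(36)
  y <- as.numeric(X %*% w_pl) + proj$intercept + rnorm(6000, sd = 0.1)
  fit <- train_positional_3mer(tibble::tibble(sequence = lib$sequence,
                                              mrl = y))
  expect_gt(cor(fit$coef, w_pl), 0.95)
  expect_identical(dim(fit$weights), c(23L, 64L))

  # all-zero targets give (numerically) zero weights
  fit0 <- train_positional_3mer(tibble::tibble(sequence = lib$sequence[1:500],
                                               mrl = rep(0, 500)))
  expect_lt(max(abs(fit0$coef)), 1e-8)

  # two replicates of one planted model agree more than an unrelated model
  y2 <- as.numeric(X0 %*% w_pl) + proj$intercept + rnorm(6000, sd = 0.1)
  rep2 <- train_positional_3mer(tibble::tibble(sequence = lib0$sequence,
                                               mrl = y2))
  other <- train_positional_3mer(
    tibble::tibble(sequence = lib$sequence,
                   mrl = as.numeric(X %*% sample(w_pl)) + rnorm(6000, 0, .1)))
  expect_gt(compare_weights(fit, rep2), compare_weights(fit, other))

  # permuted-target negative control: no weight correlation
  fitp <- train_positional_3mer(tibble::tibble(sequence = lib$sequence,
                                               mrl = sample(y)))
  expect_lt(abs(cor(fitp$coef, w_pl)), 0.2)
})

test_that("k-mer oracle filters, selects and refits as specified", {
  tab <- planted_table(4000, seed = 37, architecture = "random_end_50")
  X <- utrforge:::kmer_feature_matrix(tab$sequence)
  set.seed(38)
  pool <- colnames(X)[nchar(colnames(X)) %in% 3:5 &
                        !grepl("ATG", colnames(X))]
  planted <- sample(pool, 5)
  w <- c(0.9, -0.8, 0.7, 0.8, -0.9)
  tab$mrl <- 4 + as.numeric(as.matrix(X[, planted]) %*% w) +
    rnorm(4000, sd = 0.1)
  orc <- train_kmer_oracle(tab, min_reads = 0, exclude_uaug = FALSE,
                           exclude_initial_tg = FALSE,
                           n_train_subset = 2500, seed = 39)
  expect_true(all(planted %in% orc$selected_features))
  expect_lt(max(abs(orc$final_weights[planted] - w) / abs(w)), 0.1)
  expect_gt(orc$test_r, 0.9)

  # determinism given the seed
  orc2 <- train_kmer_oracle(tab, min_reads = 0, exclude_uaug = FALSE,
                            exclude_initial_tg = FALSE,
                            n_train_subset = 2500, seed = 39)
  expect_identical(orc$final_weights, orc2$final_weights)

  # support size is non-increasing in the penalty
  orc_big <- train_kmer_oracle(tab, min_reads = 0, exclude_uaug = FALSE,
                               exclude_initial_tg = FALSE, lasso_alpha = 0.01,
                               n_train_subset = 2500, seed = 39)
  expect_lte(length(orc_big$selected_features),
             length(orc$selected_features))
  # a huge penalty empties the support
  expect_error(
    train_kmer_oracle(tab, min_reads = 0, exclude_uaug = FALSE,
                      exclude_initial_tg = FALSE, lasso_alpha = 1e4,
                      n_train_subset = 2500, seed = 39),
    "smaller")
})

test_that("k-mer oracle exclusion filters drop uAUG and junction-TG reads", {
  base <- paste(rep("C", 48), collapse = "")
  tab <- tibble::tibble(
    variant_id = c("uaug", "tg_start", "clean"),
    sequence = c(paste0("ATG", base, substr(base, 1, 47 - 48)),
                 paste0("TG", base),
                 paste0("CA", base)),
    mrl = c(2, 3, 4), reads = 1000,
    prefix = fixed_end_default_prefix(),
    architecture = "fixed_end_50")
  tab$sequence <- substr(paste0(tab$sequence, base), 1, 50)
  keepable <- tryCatch(
    train_kmer_oracle(tab, min_reads = 250, n_train_subset = 10, seed = 1),
    error = function(e) e)
  # with only one sequence surviving both filters the pipeline refuses
  expect_s3_class(keepable, "error")
  expect_match(conditionMessage(keepable), "too few")
})
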