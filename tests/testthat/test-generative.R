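test_that("VAE training sets respect coverage and top-MRL selection", {
  tab <- planted_table(500, seed = 51, reads = rpois(500, 1000))
  ts <- build_vae_trainset(tab, coverage = 500, n_train = 100, n_test = 50,
                           top_pool = 200, seed = 2)
  expect_identical(nrow(ts$train), 100L)
  expect_identical(nrow(ts$test), 50L)
  expect_length(intersect(ts$train$variant_id, ts$test$variant_id), 0L)
  # everything selected comes from the top 200 by MRL among covered
  covered <- tab[tab$reads > 500, ]
  pool <- covered$variant_id[order(-covered$mrl)][1:200]
  expect_true(all(c(ts$train$variant_id, ts$test$variant_id) %in% pool))
  # reproducible given the seed
  ts2 <- build_vae_trainset(tab, coverage = 500, n_train = 100, n_test = 50,
                            top_pool = 200, seed = 2)
  expect_identical(ts$train$variant_id, ts2$train$variant_id)
  expect_error(build_vae_trainset(tab, coverage = 1e9), "pass coverage")
})

test_that("the VAE memorizes a single sequence and separates distributions", {
  one <- "ACGTACGTACGTACGTACGTACGTA"
  v1 <- train_vae(vae_spec(25), rep(one, 50), epochs = 60, seed = 5)
  expect_gte(v1$train_recon_accuracy, 0.99)

  # GC-biased training distribution scores higher than uniform sequences
  biased <- generate_library(1100, seed = 52,
                             base_probs = c(0.15, 0.35, 0.35, 0.15))
  v <- train_vae(vae_spec(25), biased$sequence[1:1000], epochs = 40,
                 seed = 6)
  ind <- estimate_log_likelihood(v, biased$sequence[1001:1100],
                                 seed = 7)$log_p_estimate
  unif <- estimate_log_likelihood(v, generate_library(100, seed = 53)$sequence,
                                  seed = 7)$log_p_estimate
  expect_lt(wilcox.test(ind, unif, alternative = "greater")$p.value, 0.01)

  # smoothed loss history is non-increasing
  sm <- stats::filter(v$history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.05))
  expect_lt(sm[length(sm)], sm[1])
})

test_that("likelihood estimators are seeded and importance weighting tightens", {
  lib <- generate_library(60, seed = 54)
  v <- train_vae(vae_spec(25), lib$sequence[1:50], epochs = 15, seed = 8)
  test_seqs <- lib$sequence[51:60]
  e1 <- estimate_log_likelihood(v, test_seqs, "elbo", seed = 9)
  e2 <- estimate_log_likelihood(v, test_seqs, "elbo", seed = 9)
  expect_identical(e1$log_p_estimate, e2$log_p_estimate)

  iw <- estimate_log_likelihood(v, test_seqs, "importance_weighted",
                                n_samples = 64, seed = 10)
  el <- estimate_log_likelihood(v, test_seqs, "elbo", seed = 10)
  expect_gt(mean(iw$log_p_estimate - el$log_p_estimate), 0)
  expect_error(estimate_log_likelihood(v, "ACGT"), "length mismatch")
})

test_that("margin penalty is the documented piecewise-linear hinge", {
  expect_identical(margin_penalty(-30, margin = -30), 0)
  expect_identical(margin_penalty(-40, margin = -30), 10)
  expect_identical(margin_penalty(-10, margin = -15.6), 0)
  grid <- seq(-60, 0, by = 0.5)
  pen <- margin_penalty(grid, margin = -15.6)
  expect_true(all(pen >= 0))
  expect_equal(pen, pmax(0, -15.6 - grid))
  # convex: second differences non-negative
  expect_true(all(diff(diff(pen)) > -1e-12))
  # slope -1 below the margin
  below <- grid < -16
  expect_equal(diff(pen[below]) / diff(grid[below]),
               rep(-1, sum(below) - 1))
})

test_that("generator collapses without a diversity objective and not with it", {
  set.seed(55)
  pwm <- matrix(rnorm(25 * 4), 25, 4)
  toy <- pwm_predictor(pwm)
  den0 <- train_den(den_spec(toy, 25, "maximize", diversity_weight = 0),
                    n_iter = 500, seed = 9)
  g0 <- den_generate(den0, 64, seed = 10)
  expect_gte(max(table(g0$sequence)) / 64, 0.9)

  dend <- train_den(den_spec(toy, 25, "maximize", diversity_weight = 5),
                    n_iter = 500, seed = 9)
  gd <- den_generate(dend, 64, seed = 10)
  expect_gt(mean_pairwise_norm_edit(gd$sequence),
            mean_pairwise_norm_edit(g0$sequence))

  # generated batches are sorted by predicted score and reproducible
  expect_true(!is.unsorted(-gd$predicted_mrl))
  gd2 <- den_generate(dend, 64, seed = 10)
  expect_identical(gd$sequence, gd2$sequence)
  # sorted order agrees with re-scoring from scratch
  expect_equal(gd$predicted_mrl, predict_mrl(toy, gd$sequence))

  # top-k selection helper stays inside the top k
  sel <- select_from_top(gd, n_select = 5, top_k = 20, seed = 11)
  expect_true(all(sel$sequence %in% gd$sequence[1:20]))

  # mode contracts
  expect_error(den_generate(dend, 4, seed = 1, target = 3), "target")
  deni <- den_spec(toy, 25, "inverse_regression")
  expect_error(den_generate(train_den(deni, n_iter = 5, seed = 1), 4,
                            seed = 1), "target")
})

test_that("VAE-regularized generation shifts samples toward the VAE manifold", {
  set.seed(56)
  lib <- generate_library(600, seed = 57,
                          base_probs = c(0.1, 0.4, 0.1, 0.4))
  vae <- train_vae(vae_spec(25), lib$sequence[1:500], epochs = 30, seed = 12)
  pwm <- matrix(rnorm(25 * 4, sd = 0.5), 25, 4)
  toy <- pwm_predictor(pwm)
  den0 <- train_den(den_spec(toy, 25, diversity_weight = 3),
                    n_iter = 400, seed = 13)
  denv <- train_den(den_spec(toy, 25, diversity_weight = 3, vae_weight = 2,
                             vae = vae, vae_margin = -15.6),
                    n_iter = 400, seed = 13)
  ll <- function(seqs) estimate_log_likelihood(vae, seqs,
                                               seed = 14)$log_p_estimate
  l0 <- ll(den_generate(den0, 64, seed = 15)$sequence)
  lv <- ll(den_generate(denv, 64, seed = 15)$sequence)
  expect_gt(mean(lv), mean(l0))
})
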