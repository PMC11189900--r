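test_that("library generation is seeded, sized, and composition-controlled", {
  a <- generate_library(10, seed = 1)
  b <- generate_library(10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a$sequence, generate_library(10, seed = 2)$sequence))
  expect_true(all(nchar(a$sequence) == 25))
  expect_true(all(a$prefix == "GGG"))
  expect_false(anyDuplicated(a$id) > 0)

  big <- generate_library(100000, seed = 3)
  freq <- table(strsplit(paste(big$sequence, collapse = ""), "")[[1]])
  expect_true(all(abs(freq / sum(freq) - 0.25) < 0.01))

  l50 <- generate_library(5, architecture = "random_end_50", seed = 4)
  expect_true(all(nchar(l50$sequence) == 50))
})

test_that("the planted model applies frame- and position-dependent effects", {
  params <- ground_truth_params()
  blank25 <- function(s) {
    stopifnot(nchar(s) <= 25)
    paste0(s, paste(rep("G", 25 - nchar(s)), collapse = ""))
  }
  mk <- function(s) utr_library("x", blank25(s))
  # motif-free sequence sits exactly at the baseline
  expect_equal(ground_truth_mrl(mk(""), params), params$mu0)

  # a cap-proximal uAUG is penalized less than a distal one (same frame)
  neutral <- paste(rep("G", 25), collapse = "")
  at <- function(p) { # uAUG at variable position p (transcript p + 3)
    s <- strsplit(neutral, "")[[1]]
    s[p + 1:3] <- c("A", "T", "G")
    utr_library("x", paste(s, collapse = ""))
  }
  # positions 1 and 13 are both out of frame relative to cds_offset 28
  expect_identical((28 - 4) %% 3 == 0, (28 - 16) %% 3 == 0)
  expect_gt(ground_truth_mrl(at(1), params), ground_truth_mrl(at(13), params))

  # in-frame distal uAUG penalized less than out-of-frame at a similar
  # distance (positions 15 vs 16 in variable coordinates)
  expect_equal((28 - 18) %% 3, 1)  # variable 15 -> out of frame
  expect_equal((28 - 19) %% 3, 0)  # variable 16 -> in frame
  expect_gt(ground_truth_mrl(at(16), params), ground_truth_mrl(at(15), params))

  # pyrimidine tracts boost, more near the cap
  pyr_at <- function(p) {
    s <- strsplit(neutral, "")[[1]]
    s[p + 1:5] <- "T"
    utr_library("x", paste(s, collapse = ""))
  }
  expect_gt(ground_truth_mrl(pyr_at(0), params), params$mu0)
  expect_gt(ground_truth_mrl(pyr_at(0), params),
            ground_truth_mrl(pyr_at(15), params))

  # noise is seeded and has the configured scale
  lib <- generate_library(4000, seed = 5)
  n1 <- ground_truth_mrl(lib, params, with_noise = TRUE, seed = 9)
  n2 <- ground_truth_mrl(lib, params, with_noise = TRUE, seed = 9)
  expect_identical(n1, n2)
  clean <- ground_truth_mrl(lib, params)
  expect_equal(sd(n1 - clean), params$noise_sigma, tolerance = 0.05)
})

test_that("fraction count simulation matches occupancy and free-fraction links", {
  lib <- generate_library(50, seed = 11)
  mrl <- runif(50, 1.5, 7.4)
  sim <- simulate_fraction_counts(lib, mrl, depth_per_fraction = 2e4,
                                  seed = 12)
  # seeded reproducibility
  sim2 <- simulate_fraction_counts(lib, mrl, depth_per_fraction = 2e4,
                                   seed = 12)
  expect_identical(sim$counts$count, sim2$counts$count)

  # occupancy rows are truncated-Poisson pmfs with the requested means
  means <- as.numeric(sim$occupancy %*% (1:8))
  expect_equal(means, mrl, tolerance = 1e-6)

  # out-of-range targets refuse
  expect_error(simulate_fraction_counts(lib, rep(0.5, 50)), "truncated-Poisson")
  expect_error(simulate_fraction_counts(lib, rep(8, 50)), "truncated-Poisson")

  # free fraction: phi = 0 yields no free counts
  params0 <- ground_truth_params(free_base = 1e-9, free_span = 1e-9)
  simf <- simulate_fraction_counts(lib, mrl, params = params0,
                                   depth_per_fraction = 1e3,
                                   include_free = TRUE, seed = 13)
  expect_true(all(simf$counts$count[simf$counts$fraction_id == "free"] %in%
                    0:1))
})

test_that("read simulation round-trips through filtering and UMI collapse", {
  lib <- generate_library(25, seed = 21)
  mrl <- runif(25, 2, 7)
  sim <- simulate_fraction_counts(lib, mrl, depth_per_fraction = 250,
                                  seed = 22)
  want <- dplyr::arrange(tibble::as_tibble(sim$counts)[sim$counts$count > 0, ],
                         variant_id, fraction_id)

  # zero duplication, zero error: exact identity
  reads <- simulate_reads(sim$counts, seed = 23)
  got <- collapse_umis(parse_and_filter_reads(reads, "ATGGG"),
                       fractions = attr(sim$counts, "fractions"))
  got <- dplyr::arrange(tibble::as_tibble(got), variant_id, fraction_id)
  expect_identical(as.integer(got$count), as.integer(want$count))

  # duplicates collapse back exactly
  reads_dup <- simulate_reads(sim$counts, duplication_rate = 0.5, seed = 24)
  expect_gt(nrow(reads_dup), nrow(reads))
  got_dup <- collapse_umis(parse_and_filter_reads(reads_dup, "ATGGG"),
                           fractions = attr(sim$counts, "fractions"))
  got_dup <- dplyr::arrange(tibble::as_tibble(got_dup), variant_id,
                            fraction_id)
  expect_identical(as.integer(got_dup$count), as.integer(want$count))

  # UMI sequencing errors are absorbed to within 1% of total counts
  reads_err <- simulate_reads(sim$counts, duplication_rate = 0.6,
                              error_rate = 0.03, seed = 25)
  got_err <- collapse_umis(parse_and_filter_reads(reads_err, "ATGGG"),
                           fractions = attr(sim$counts, "fractions"))
  expect_lt(abs(sum(got_err$count) - sum(want$count)) / sum(want$count),
            0.01)

  # low-quality reads are manufactured and filtered at the q threshold
  reads_q <- simulate_reads(sim$counts, q_fail_fraction = 0.3, seed = 26)
  kept <- parse_and_filter_reads(reads_q, "ATGGG")
  expect_equal(nrow(kept) / nrow(reads_q), 0.7, tolerance = 0.05)
  expect_true(all(kept$mean_q > 25))

  # seeded reproducibility
  expect_identical(simulate_reads(sim$counts, seed = 23),
                   simulate_reads(sim$counts, seed = 23))
})

test_that("high-depth count simulation makes compute_mrl consistent", {
  set.seed(31)
  lib <- generate_library(100, seed = 32)
  mrl <- runif(100, 1.5, 7.4)
  sim <- simulate_fraction_counts(lib, mrl,
                                  depth_per_fraction = round(1e7 / 8),
                                  seed = 33)
  rec <- compute_mrl(sim$counts)
  err <- abs(rec$mrl[match(lib$id, rec$variant_id)] - mrl)
  expect_lt(max(err), 0.05)
})

test_that("free-to-total ratios anti-correlate with planted MRL", {
  lib <- generate_library(200, seed = 41)
  mrl <- runif(200, 1.5, 7.4)
  sim <- simulate_fraction_counts(lib, mrl, depth_per_fraction = 2e5,
                                  include_free = TRUE, seed = 42)
  ft <- free_to_total_ratio(sim$free_counts$count,
                            pmax(sim$total_counts$count, 1))
  expect_lt(cor(ft, mrl, method = "spearman"), -0.8)
})

test_that("the full pipeline supports training a predictive model", {
  # planted truth -> occupancy counts -> MRL recovery -> CNN training;
  # problem size chosen for desk-scale runtimes (see the methods vignette)
  lib <- generate_library(30000, seed = 101)
  truth <- ground_truth_mrl(lib, with_noise = TRUE, seed = 102)
  clipped <- pmin(pmax(truth, 1.1), 7.9)
  sim <- simulate_fraction_counts(lib, clipped, depth_per_fraction = 3e6,
                                  seed = 103)
  rec <- compute_mrl(sim$counts)
  expect_gt(cor(rec$mrl, clipped[match(rec$variant_id, lib$id)]), 0.99)

  tab <- dplyr::inner_join(
    rec, tibble::tibble(variant_id = lib$id, sequence = lib$sequence),
    by = "variant_id")
  sp <- make_split(tab, 2000, 2000)
  cnn <- train_cnn(cnn_spec(), sp, max_epochs = 12, patience = 3, seed = 6)
  pred <- predict_mrl(cnn, sp$test$sequence)
  expect_gte(evaluate_r2(pred, sp$test$mrl), 0.7)
})
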