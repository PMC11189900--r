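test_that("read filtering applies the quality and TS-oligo rules", {
  reads <- tibble::tibble(
    variant_id = "v", fraction_id = "rib1",
    umi = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"),
    mean_q = c(24, 30, 30, 30),
    ts_suffix = c("ATGGG",        # dropped on quality alone
                  "ATGGG",        # exact match, kept
                  "TTTTTTTTTT",   # edit distance > 5, dropped
                  "GGGGG"))       # distance 5 from ATGGG x ... kept iff <= 5
  out <- parse_and_filter_reads(reads, ts_oligo = "ATGGG")
  expect_identical(out$umi, c("CCCCCCCCCC", "TTTTTTTTTT"))
  log <- attr(out, "filter_log")
  expect_identical(unname(log["low_quality"]), 1L)
  expect_identical(unname(log["ts_mismatch"]), 1L)

  # boundary: distance exactly 5 retained, 6 dropped; q exactly 25 dropped
  b <- tibble::tibble(variant_id = "v", fraction_id = "f", umi = "AAAAAAAAAA",
                      mean_q = c(25, 26, 26),
                      ts_suffix = c("ATGGG", "CCCCC", "CCCCCC"))
  kept <- parse_and_filter_reads(b, ts_oligo = "ATGGG")
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$ts_suffix, "CCCCC")

  expect_warning(parse_and_filter_reads(b[0, ], ts_oligo = "ATGGG"),
                 "no reads")
  # fixed-end path: no TS check
  expect_identical(nrow(parse_and_filter_reads(b, ts_oligo = NULL)), 2L)
})

test_that("UMI collapse merges duplicates and Hamming-1 neighbours", {
  fr1 <- tibble::tibble(fraction_id = "rib1", ribosome_load = 1,
                        is_free = FALSE)
  mk <- function(umis) tibble::tibble(variant_id = "v", fraction_id = "rib1",
                                      umi = umis)
  expect_identical(collapse_umis(mk(rep("AAAAAAAAAA", 3)), fr1)$count, 1L)
  expect_identical(
    collapse_umis(mk(c(rep("AAAAAAAAAA", 5), "AAAAAAAAAT")), fr1)$count, 1L)
  expect_identical(
    collapse_umis(mk(c("AAAAAAAAAA", "AAAAAAAATT")), fr1)$count, 2L)
  expect_error(collapse_umis(mk(c("AAAA", "AAAAA")), fr1), "ragged")

  # directional: two singletons at distance 1 merge into one cluster;
  # a chain A(5) - B(1) - C(1) with d(A,C)=2 collapses fully through B
  expect_identical(
    collapse_umis(mk(c(rep("AAAAAAAAAA", 5), "AAAAAAAAAT", "AAAAAAAAGT")),
                  fr1)$count, 1L)
})

test_that("compute_mrl implements the three-step formula exactly", {
  fc <- fraction_counts(
    tibble::tibble(variant_id = rep(c("v1", "x"), each = 3),
                   fraction_id = rep(c("rib1", "rib2", "rib3"), 2),
                   count = c(10, 10, 40, 90, 90, 160)),
    fractions = fraction_specs(1:3))
  res <- compute_mrl(fc)
  # fraction totals are (100, 100, 200): v1 normalizes to (.1, .1, .2)
  expect_equal(res$mrl[res$variant_id == "v1"], (0.1 + 0.2 + 0.6) / 0.4)

  # a variant entirely in the load-3 fraction has MRL exactly 3
  fc3 <- fraction_counts(
    tibble::tibble(variant_id = c("a", "a", "a", "b", "b", "b"),
                   fraction_id = rep(c("rib1", "rib2", "rib3"), 2),
                   count = c(0, 0, 50, 10, 10, 10)),
    fractions = fraction_specs(1:3))
  r3 <- compute_mrl(fc3)
  expect_equal(r3$mrl[r3$variant_id == "a"], 3)

  expect_error(compute_mrl(fc3[fc3$fraction_id != "rib2", ]), "rib2")
})

test_that("compute_mrl matches an independent brute-force oracle", {
  set.seed(11)
  max_diff <- 0
  for (i in 1:1000) {
    sim <- random_fraction_counts(n_var = 8)
    got <- compute_mrl(sim$fc)
    want <- brute_mrl(sim$matrix, sim$loads)
    ord <- match(sprintf("v%03d", 1:8), got$variant_id)
    max_diff <- max(max_diff, abs(got$mrl[ord] - want))
    # bounded by the loads with nonzero counts
    expect_true(all(got$mrl >= 1 & got$mrl <= 8))
  }
  expect_lt(max_diff, 1e-12)
})

test_that("MRL is invariant to per-fraction count rescaling", {
  set.seed(12)
  for (i in 1:50) {
    sim <- random_fraction_counts(n_var = 6)
    scaled <- sim$fc
    scaled$count <- ifelse(scaled$fraction_id == "rib3",
                           scaled$count * 10L, scaled$count)
    scaled <- fraction_counts(scaled, fractions = fraction_specs(sim$loads))
    expect_equal(compute_mrl(sim$fc)$mrl, compute_mrl(scaled)$mrl,
                 tolerance = 1e-12)
  }
})

test_that("replicate filtering and weighted averaging follow the contract", {
  r1 <- tibble::tibble(variant_id = c("a", "b"), mrl = c(2, 4),
                       total_reads = c(150, 120), replicate_id = "r1")
  r2 <- tibble::tibble(variant_id = c("a", "b"), mrl = c(3, 5),
                       total_reads = c(80, 300), replicate_id = "r2")
  out <- filter_and_average_replicates(list(r1, r2), min_reads = 100)
  # 'a' has 80 reads in replicate 2 -> excluded
  expect_identical(out$variant_id, "b")
  expect_equal(out$mrl, (4 * 120 + 5 * 300) / 420)
  expect_equal(out$reads, 420)

  # weighted mean example: (2.0, w=100), (3.0, w=300) -> 2.75
  s1 <- tibble::tibble(variant_id = "v", mrl = 2, total_reads = 100,
                       replicate_id = "r1")
  s2 <- tibble::tibble(variant_id = "v", mrl = 3, total_reads = 300,
                       replicate_id = "r2")
  expect_equal(filter_and_average_replicates(list(s1, s2))$mrl, 2.75)

  # single replicate: identity
  expect_equal(filter_and_average_replicates(list(s1))$mrl, 2)
  # order invariance
  expect_identical(filter_and_average_replicates(list(s1, s2)),
                   filter_and_average_replicates(list(s2, s1)))
  expect_warning(
    filter_and_average_replicates(list(s1), min_reads = 1e6), "no variant")
})

test_that("positional medians recover the planted positional uAUG effect", {
  lib <- generate_library(20000, seed = 91)
  mrl <- ground_truth_mrl(lib, with_noise = TRUE, seed = 92)
  tab <- join_sequences(tibble::tibble(variant_id = lib$id, mrl = mrl), lib)
  eff <- positional_median_effect(tab, "uaug", min_sequences = 20)
  ok <- !is.na(eff$normalized_median)
  p <- eff$position[ok]
  gt <- ground_truth_params()
  delta <- ifelse((28 - p) %% 3 == 0, gt$if_max, gt$oof_max) *
    (1 - exp(-pmax(p - 3, 0) / gt$attenuation_nt))
  expect_lt(cor(delta, eff$normalized_median[ok], method = "spearman"), -0.9)

  # out-of-frame penalties exceed in-frame ones away from the cap
  distal <- p >= 12
  oof <- distal & (28 - p) %% 3 != 0
  inf <- distal & (28 - p) %% 3 == 0
  expect_lt(mean(eff$normalized_median[ok][oof]),
            mean(eff$normalized_median[ok][inf]))

  # uAUG positions carry significantly lower MRL than the rest
  expect_lt(min(eff$p_value[ok][oof]), 1e-6)

  # degenerate: identical MRLs normalize to exactly 1
  tab2 <- dplyr::mutate(tab, mrl = 3)
  e2 <- positional_median_effect(tab2, "uaug", min_sequences = 20,
                                 test = FALSE)
  expect_true(all(abs(
    e2$normalized_median[!is.na(e2$normalized_median)] - 1) < 1e-12))

  # a position with too few matches is reported but NA-valued
  e3 <- positional_median_effect(tab[1:60, ], "uaug", min_sequences = 50)
  expect_true(any(is.na(e3$normalized_median)))
})
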