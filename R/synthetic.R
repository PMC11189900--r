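#' Planted ground-truth sequence-to-MRL model
#'
#' Parameters of the synthetic regulatory model every pipeline is tested
#' against. The model is an explicit stand-in — not a biophysical claim —
#' that reproduces the qualitative structure of 5'UTR translation
#' regulation: upstream AUGs repress translation, more strongly out of
#' frame than in frame and more weakly very close to the 5' cap (where
#' scanning has not fully engaged), while short oligopyrimidine tracts near
#' the cap give a small boost that decays with distance. The ground-truth
#' MRL of a sequence is
#' `mu0 - sum(uAUG penalties) + sum(pyrimidine-tract boosts)`, clipped at
#' 0.1, plus optional Gaussian observation noise.
#'
#' @param mu0 Baseline MRL of a motif-free sequence (default 5.5, typical
#'   of a library median with 8 polysome fractions).
#' @param oof_max Plateau penalty of an out-of-frame uAUG (default 2.8).
#' @param if_max Plateau penalty of an in-frame uAUG (default 1.0; weaker,
#'   reflecting preserved reading frame).
#' @param attenuation_nt Exponential length scale (nt) over which uAUG
#'   penalties grow from 0 at the cap to their plateau (default 6).
#' @param pyr_max Boost of a 5-nt pyrimidine tract starting at the cap
#'   (default 0.25; a small effect).
#' @param pyr_decay_nt Exponential decay length (nt) of the tract boost
#'   with distance from the cap (default 10).
#' @param noise_sigma Gaussian observation noise SD in MRL units
#'   (default 0.3).
#' @param free_base,free_span,free_mid,free_scale Parameters of the
#'   monotone logistic link from MRL to the ribosome-free probability
#'   `phi = free_base + free_span * plogis((free_mid - mrl)/free_scale)`.
#' @return A `ground_truth_params` list.
#' @export
ground_truth_params <- function(mu0 = 5.5, oof_max = 2.8, if_max = 1.0,
                                attenuation_nt = 6, pyr_max = 0.25,
                                pyr_decay_nt = 10, noise_sigma = 0.3,
                                free_base = 0.03, free_span = 0.55,
                                free_mid = 3.5, free_scale = 0.8) {
  stopifnot(mu0 > 0, oof_max >= 0, if_max >= 0, pyr_max >= 0,
            noise_sigma >= 0, free_base > 0,
            free_base + free_span < 1)
  structure(list(mu0 = mu0, oof_max = oof_max, if_max = if_max,
                 attenuation_nt = attenuation_nt, pyr_max = pyr_max,
                 pyr_decay_nt = pyr_decay_nt, noise_sigma = noise_sigma,
                 free_base = free_base, free_span = free_span,
                 free_mid = free_mid, free_scale = free_scale),
            class = "ground_truth_params")
}

#' Seeded random 5'UTR library
#'
#' Generates `n` i.i.d. random variable regions with unique ids, optionally
#' with composition bias (per-base sampling weights).
#'
#' @param n Number of variants.
#' @param architecture Library architecture (fixes the variable-region
#'   length).
#' @param seed Generation seed.
#' @param base_probs Sampling weights for (A, C, G, T); default uniform.
#' @param prefix Optional constant prefix override (see [utr_library()]).
#' @return A [utr_library()] tibble.
#' @export
generate_library <- function(n, architecture = "random_end_25", seed = 1L,
                             base_probs = c(0.25, 0.25, 0.25, 0.25),
                             prefix = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  L <- arch_length(architecture)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * L, replace = TRUE,
                       prob = base_probs / sum(base_probs)), n, L)
  seqs <- apply(mat, 1, paste, collapse = "")
  utr_library(sprintf("u%06d", seq_len(n)), seqs,
              architecture = architecture, prefix = prefix)
}

#' Ground-truth MRL of 5'UTR sequences
#'
#' Evaluates the planted model of [ground_truth_params()] on each variant:
#' scans the transcript (prefix + variable region) for upstream AUGs and
#' 5-nt pyrimidine tracts, applies position- and frame-dependent penalties
#' and boosts, clips at 0.1, and optionally adds Gaussian noise.
#'
#' @param lib A [utr_library()] (or tibble with `sequence`, `prefix`,
#'   `cds_offset`).
#' @param params A [ground_truth_params()].
#' @param with_noise Add `N(0, noise_sigma)` observation noise?
#' @param seed Noise seed (only used when `with_noise`).
#' @return Numeric vector of MRLs, aligned with the rows of `lib`.
#' @export
ground_truth_mrl <- function(lib, params = ground_truth_params(),
                             with_noise = FALSE, seed = 1L) {
  stopifnot(length(unique(nchar(lib$prefix))) == 1L,
            length(unique(lib$cds_offset)) == 1L)
  transcripts <- paste0(lib$prefix, lib$sequence)
  cds <- lib$cds_offset[1]
  prefix_len <- nchar(lib$prefix[1])
  n <- length(transcripts)
  mu <- rep(params$mu0, n)
  # uAUG penalties, vectorized over the library one position at a time
  for (p in 0:(cds - 3L)) {
    hit <- substring(transcripts, p + 1L, p + 3L) == "ATG"
    if (any(hit)) {
      plateau <- if ((cds - p) %% 3L == 0L) params$if_max else params$oof_max
      mu[hit] <- mu[hit] -
        plateau * uaug_attenuation(p, prefix_len, params$attenuation_nt)
    }
  }
  # 5-nt pyrimidine-tract boosts (tracts fully upstream of the CDS)
  if (cds >= 5L) {
    for (p in 0:(cds - 5L)) {
      hit <- !grepl("[AG]", substring(transcripts, p + 1L, p + 5L))
      if (any(hit)) {
        mu[hit] <- mu[hit] + pyr_boost(p, prefix_len, params)
      }
    }
  }
  mu <- pmax(mu, 0.1)
  if (with_noise) {
    set.seed(seed)
    mu <- mu + rnorm(n, sd = params$noise_sigma)
  }
  mu
}

# penalty growth from the cap: 0 at the first variable position, plateau
# attenuation_nt downstream
uaug_attenuation <- function(position, prefix_len, scale_nt) {
  1 - exp(-pmax(position - prefix_len, 0) / scale_nt)
}

pyr_boost <- function(position, prefix_len, params) {
  params$pyr_max * exp(-pmax(position - prefix_len, 0) / params$pyr_decay_nt)
}

# Ribosome-free probability of the planted free-fraction link.
free_fraction_prob <- function(mrl, params) {
  params$free_base + params$free_span *
    stats::plogis((params$free_mid - mrl) / params$free_scale)
}

# Truncated-Poisson occupancy over loads 1..F with a given conditional
# mean, solved for lambda by monotone bisection.
truncated_poisson_pmf <- function(lambda, F_max) {
  p <- stats::dpois(1:F_max, lambda)
  p / sum(p)
}

truncated_poisson_mean <- function(lambda, F_max) {
  sum((1:F_max) * truncated_poisson_pmf(lambda, F_max))
}

solve_truncated_poisson <- function(target_mean, F_max, tol = 1e-9) {
  lo <- 1e-12; hi <- 1
  while (truncated_poisson_mean(hi, F_max) < target_mean && hi < 1e6) {
    hi <- hi * 2
  }
  if (truncated_poisson_mean(hi, F_max) < target_mean) {
    abort(sprintf("target MRL %.3f not achievable with %d fractions",
                  target_mean, F_max))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (truncated_poisson_mean(mid, F_max) < target_mean) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate polysome-fraction UMI counts from true MRLs
#'
#' For each variant, the occupancy over loads 1..`n_fractions` is a
#' truncated Poisson whose conditional mean equals the variant's true MRL
#' (single-parameter family solved by bisection); the ribosome-free
#' probability comes from the planted free-fraction link. Reads are then
#' drawn multinomially per fraction to the requested depths. The
#' per-variant input representation is balanced (iterative proportional
#' fitting) so that every loaded fraction carries equal expected sequencing
#' mass — the regime in which fraction-share normalization makes
#' [compute_mrl()] an exact estimator of the planted MRL; see the methods
#' vignette.
#'
#' @param lib A [utr_library()].
#' @param true_mrl Numeric vector of true MRLs, each in (1, n_fractions).
#' @param params [ground_truth_params()] (for the free-fraction link).
#' @param n_fractions Number of loaded fractions (loads 1..F, default 8).
#' @param depth_per_fraction Reads sequenced per loaded fraction.
#' @param include_free Also simulate the ribosome-free fraction and a
#'   total-RNA library (for free-to-total analyses)?
#' @param seed Simulation seed.
#' @return A list: `counts` (a [fraction_counts()] object),
#'   `occupancy` (variant x load matrix of conditional probabilities),
#'   `representation` (balanced input weights) and, when `include_free`,
#'   `free_counts` / `total_counts` tibbles.
#' @export
simulate_fraction_counts <- function(lib, true_mrl,
                                     params = ground_truth_params(),
                                     n_fractions = 8L,
                                     depth_per_fraction = 1e5,
                                     include_free = FALSE, seed = 1L) {
  n <- nrow(lib)
  stopifnot(length(true_mrl) == n)
  eps <- 1e-3
  if (any(true_mrl <= 1 + eps | true_mrl >= n_fractions - eps)) {
    abort(sprintf(
      "true MRLs must lie in (%g, %g) to be matchable by a truncated-Poisson occupancy",
      1 + eps, n_fractions - eps))
  }
  set.seed(seed)
  Q <- t(vapply(true_mrl, function(m) {
    truncated_poisson_pmf(solve_truncated_poisson(m, n_fractions),
                          n_fractions)
  }, numeric(n_fractions)))
  rep_w <- balance_representation(Q)
  shares <- rep_w * Q                      # variant x fraction mass
  counts_list <- lapply(seq_len(n_fractions), function(f) {
    c_f <- as.integer(rmultinom(1, size = depth_per_fraction,
                                prob = shares[, f]))
    tibble(variant_id = lib$id, fraction_id = paste0("rib", f),
           count = c_f)
  })
  counts <- bind_rows(counts_list)
  fractions <- fraction_specs(seq_len(n_fractions), free = include_free)
  out <- list(occupancy = Q, representation = rep_w)
  if (include_free) {
    phi <- free_fraction_prob(true_mrl, params)
    free_mass <- rep_w * phi / (1 - phi)   # free RNA relative to loaded
    # the free library is sequenced in proportion to its RNA mass relative
    # to a loaded fraction, so an empty free peak yields (near-)zero counts
    per_fraction_mass <- mean(colSums(rep_w * Q))
    free_depth <- round(depth_per_fraction * sum(free_mass) /
                          per_fraction_mass)
    free_counts <- if (free_depth > 0) {
      as.integer(rmultinom(1, size = free_depth, prob = free_mass))
    } else rep(0L, n)
    counts <- bind_rows(counts,
                        tibble(variant_id = lib$id, fraction_id = "free",
                               count = free_counts))
    total_mass <- rep_w / (1 - phi)        # loaded + free
    out$total_counts <- tibble(
      variant_id = lib$id,
      count = as.integer(rmultinom(1, size = depth_per_fraction,
                                   prob = total_mass)))
    out$free_counts <- tibble(variant_id = lib$id, count = free_counts)
  }
  out$counts <- fraction_counts(counts, fractions = fractions,
                                replicate_id = "sim", cell_type = "synthetic")
  out
}

# Per-variant representation weights a > 0 such that the column masses of
# a * Q are equal (minimum-norm correction in the row space of Q, with
# clipping iterations to stay positive).
# Multiplicative (EM-style) updates minimizing the KL divergence of the
# column masses from uniform; stays positive and converges to the balanced
# solution whenever one exists.
balance_representation <- function(Q, n_iter = 5000L, tol = 1e-9) {
  a <- rep(1, nrow(Q))
  target <- mean(colSums(Q))
  for (it in seq_len(n_iter)) {
    M <- colSums(a * Q)
    if (max(abs(M / target - 1)) < tol) break
    a <- a * as.numeric(Q %*% (target / M))
  }
  a
}

#' Expand fraction counts into synthetic sequencing reads
#'
#' Each UMI count becomes one molecule with a random UMI (pairwise Hamming
#' distance >= 2 within a (variant, fraction) group, so zero-error read
#' sets collapse back to exactly the input counts); molecules are expanded
#' into `1 + Geometric(duplication_rate)` duplicate reads; sequencing
#' errors hit the UMI and the template-switch suffix at `error_rate` per
#' read; mean q-scores are drawn so that `q_fail_fraction` of reads fails
#' the quality filter.
#'
#' @param counts A [fraction_counts()] object.
#' @param umi_length UMI length in nt (default 10).
#' @param duplication_rate Probability parameter of the geometric duplicate
#'   count (0 = no duplicates).
#' @param error_rate Per-read probability of a single-base error in the UMI
#'   (and independently in the TS suffix).
#' @param ts_oligo Template-switching oligo appended upstream of the
#'   variable region (observed in read 1).
#' @param q_fail_fraction Fraction of reads drawn below the q = 25
#'   threshold (default 0).
#' @param seed Simulation seed.
#' @return Read tibble for [parse_and_filter_reads()] /
#'   [collapse_umis()].
#' @export
simulate_reads <- function(counts, umi_length = 10L, duplication_rate = 0,
                           error_rate = 0, ts_oligo = "ATGGG",
                           q_fail_fraction = 0, seed = 1L) {
  stopifnot(duplication_rate >= 0, duplication_rate < 1,
            error_rate >= 0, error_rate < 1)
  set.seed(seed)
  groups <- counts[counts$count > 0, , drop = FALSE]
  rows <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    k <- groups$count[g]
    umis <- draw_spaced_umis(k, umi_length)
    dup <- 1L + if (duplication_rate > 0) {
      stats::rgeom(k, prob = 1 - duplication_rate)
    } else rep(0L, k)
    umi_reads <- rep(umis, dup)
    n_reads <- length(umi_reads)
    if (error_rate > 0) {
      hit <- runif(n_reads) < error_rate
      umi_reads[hit] <- vapply(umi_reads[hit], mutate_one_base, character(1))
    }
    ts <- rep(ts_oligo, n_reads)
    if (error_rate > 0) {
      hit <- runif(n_reads) < error_rate
      ts[hit] <- vapply(ts[hit], mutate_one_base, character(1))
    }
    mean_q <- ifelse(runif(n_reads) < q_fail_fraction,
                     runif(n_reads, 15, 25), runif(n_reads, 28, 40))
    rows[[g]] <- tibble(variant_id = groups$variant_id[g],
                        fraction_id = groups$fraction_id[g],
                        umi = umi_reads, ts_suffix = ts, mean_q = mean_q)
  }
  out <- bind_rows(rows)
  out[sample.int(nrow(out)), , drop = FALSE]
}

# k random UMIs, pairwise Hamming distance >= 2 (rejection sampling)
draw_spaced_umis <- function(k, umi_length) {
  bases <- c("A", "C", "G", "T")
  out <- character(k)
  taken <- new.env(parent = emptyenv(), hash = TRUE)
  i <- 1L
  while (i <= k) {
    u <- paste(sample(bases, umi_length, replace = TRUE), collapse = "")
    nb <- hamming1_neighbors(u)
    clash <- FALSE
    for (v in nb) if (!is.null(taken[[v]])) { clash <- TRUE; break }
    if (!clash) {
      out[i] <- u
      for (v in nb) taken[[v]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

mutate_one_base <- function(s) {
  chars <- strsplit(s, "")[[1]]
  i <- sample.int(length(chars), 1L)
  chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Simulate spike-in calibrated decay kinetics
#'
#' Generates the three tables consumed by [normalize_series()]: per-variant
#' counts across timepoints under biphasic exponential decay
#' `A * (w * exp(-k_fast * t) + (1 - w) * exp(-k_slow * t))`, spike-in
#' control counts proportional to their concentrations, and an
#' untransfected input library. Per-timepoint library depths vary (and can
#' carry a power distortion) to exercise the calibration; counts are
#' Poisson draws unless `noiseless`.
#'
#' @param variants Tibble with `variant_id`, `A`, `w`, `k_fast`, `k_slow`
#'   and optionally `input_weight` (initial loading differences).
#' @param timepoints_h Sampling times in hours (default
#'   `c(0.5, 1, 2, 4, 8, 24)`).
#' @param spike_concentrations Relative spike concentrations (default
#'   `10^(0:4)`).
#' @param depth Expected reads for the most abundant spike-in per
#'   timepoint.
#' @param depth_jitter_sd SD of the lognormal per-timepoint depth factor.
#' @param distortion_range Per-timepoint power distortion exponents are
#'   drawn uniformly in this range (c(1, 1) disables distortion).
#' @param noiseless Return expected (non-integer) counts instead of
#'   Poisson draws.
#' @param seed Simulation seed.
#' @return List of tibbles `raw_counts`, `spikes`, `input_library`, plus
#'   `truth` (the noise-free abundance series).
#' @export
simulate_decay <- function(variants, timepoints_h = c(0.5, 1, 2, 4, 8, 24),
                           spike_concentrations = 10^(0:4), depth = 1e5,
                           depth_jitter_sd = 0.2,
                           distortion_range = c(1, 1), noiseless = FALSE,
                           seed = 1L) {
  stopifnot(all(diff(timepoints_h) > 0),
            all(diff(spike_concentrations) > 0))
  if (!"input_weight" %in% names(variants)) variants$input_weight <- 1
  stopifnot(all(variants$w >= 0 & variants$w <= 1),
            all(variants$k_fast > 0), all(variants$k_slow > 0))
  set.seed(seed)
  top <- max(spike_concentrations)
  truth <- tidyr::expand_grid(variant_id = variants$variant_id,
                              timepoint_h = timepoints_h) |>
    left_join(variants, by = "variant_id") |>
    mutate(abundance = .data$A * (.data$w * exp(-.data$k_fast * .data$timepoint_h) +
                                    (1 - .data$w) * exp(-.data$k_slow * .data$timepoint_h))) |>
    select("variant_id", "timepoint_h", "abundance")
  draw <- function(mu) if (noiseless) mu else rpois(length(mu), mu)
  spikes <- list(); raw <- list()
  for (i in seq_along(timepoints_h)) {
    t <- timepoints_h[i]
    d_t <- exp(rnorm(1, sd = depth_jitter_sd))
    gamma_t <- runif(1, distortion_range[1], distortion_range[2])
    mu_spike <- (depth * d_t * spike_concentrations / top)^gamma_t
    spikes[[i]] <- tibble(timepoint_h = t,
                          relative_concentration = spike_concentrations,
                          count = draw(mu_spike))
    ab <- truth$abundance[truth$timepoint_h == t]
    # variants are loaded at abundances comparable to the top spike-in, so
    # A ~ 1 corresponds to ~`depth` expected reads at t = 0
    mu_var <- (depth * d_t * ab * variants$input_weight)^gamma_t
    raw[[i]] <- tibble(variant_id = variants$variant_id, timepoint_h = t,
                       count = draw(mu_var))
  }
  input_mu <- 1e5 * variants$input_weight / sum(variants$input_weight)
  list(raw_counts = bind_rows(raw), spikes = bind_rows(spikes),
       input_library = tibble(variant_id = variants$variant_id,
                              count = draw(input_mu)),
       truth = truth)
}
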