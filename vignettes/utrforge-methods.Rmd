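---
title: "Models and methods behind utrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind utrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

utrforge is a toolkit for engineering 5' untranslated regions (5'UTRs) that
tune how efficiently an mRNA is translated. It covers the full loop of a
model-guided design campaign: quantify translation for hundreds of thousands
of 5'UTR variants with a polysome-profiling MPRA, fit sequence-to-activity
models on those measurements, invert the models to design new sequences, and
analyse what designed mRNAs do downstream (stability kinetics and
gene-editing output). This vignette explains the models, the numerical
choices, and what the synthetic test bed does and does not demonstrate.

## Mean ribosome load

Polysome profiling separates mRNAs on a sucrose gradient by the number of
ribosomes bound. Sequencing each fraction's library gives UMI counts
$c_{vf}$ for variant $v$ in fraction $f$, and translation efficiency is
summarized as the mean ribosome load

$$\mathrm{MRL}_v
  = \frac{\sum_f (c_{vf}/N_f)\, r_f}{\sum_f (c_{vf}/N_f)},$$

where $N_f$ is the fraction's total count and $r_f$ its ribosome load
(defaults 1..8; the number of collected fractions and the load assigned to
the heaviest are experiment configuration). The three steps — normalize each
fraction to its sequencing depth, weight by ribosome numbers, divide by the
unweighted normalized sum — make the statistic invariant to how deeply any
single fraction was sequenced, which `compute_mrl()`'s tests assert
explicitly. The ribosome-free fraction is carried through the containers but
excluded from the MRL sums: MRL only describes mRNAs engaged by at least one
ribosome, and the free fraction instead feeds the free-to-total ratio
(`free_to_total_ratio()`), a separate signal for translationally inactive
mRNA.

Upstream of MRL, reads are kept when their mean base quality exceeds 25 and
(for template-switching libraries, which have no constant 5' end to prime
from) when the bases adjacent to the template-switch junction match the
expected oligo within 5 Levenshtein edits. UMIs are collapsed by a
deterministic directional scheme: exact duplicates merge, then any UMI
within Hamming distance 1 of a more abundant one merges into it, visiting
UMIs in descending count order with lexicographic tie-breaks. This is a
reproducible, dependency-free restatement of what dedicated UMI-clustering
tools do at these UMI lengths and depths; its merge decisions chain, so a
singleton a further base away can still be absorbed through an intermediate.

Replicates are combined by keeping variants with at least 100 reads in
every replicate (the per-replicate sum over fractions) and averaging MRL
weighted by each replicate's read depth.

## Predictors

Three model families predict MRL from sequence, each with a different role.

**The convolutional network** (`cnn_spec()`, `train_cnn()`) is the designer's
predictor. The architecture family is VGG-style: 1-5 blocks of two
length-preserving convolutions (ReLU), max pooling with size and stride 2,
and dropout; then one dense ReLU layer and a linear output node, with
filters doubling between blocks. Defaults (2 blocks, 16 base filters,
kernel 5, 50 dense units) sit inside the family's stated hyperparameter
ranges and are small enough to train in minutes on one CPU. Training
minimizes MSE with Adam (learning rate 1e-3, batch 128, optional decoupled
weight decay) and early-stops on validation loss; the best-epoch weights
are kept. Inputs are one-hot encoded over the fixed channel order
(A, C, G, T) and zero-padded on the left when shorter than the input width.
Train/validation/test splits rank variants by read depth — the held-out top
2,000 are the most precisely measured sequences, so test-set performance is
not depressed by measurement noise — with ties broken by variant id for
determinism.

The network engine itself (forward, backward, Adam) is a compact in-package
implementation in base matrix algebra. It is single-threaded, bitwise
reproducible given a seed, and exposes gradients with respect to the input
matrix, which the design algorithms require.

**The positional 3-mer linear model** (`train_positional_3mer()`) regresses
MRL on one indicator per (offset, 3-mer). Its purpose is interpretability —
comparing weight vectors across replicates or cell types by Pearson
correlation. The indicator design is structurally collinear: the 64
indicators at each offset sum to one, and overlapping windows impose
telescoping constraints between adjacent offsets. We therefore solve the
centered normal equations with a tiny ridge stabilizer (1e-6 on the
diagonal), which returns the minimum-norm representative; only the
identifiable component of a weight vector is estimable, and the recovery
harness plants weights inside that space (by projecting a random vector
through a noiseless fit on an independent library) before asking for
recovery under noise.

**The k-mer oracle** (`train_kmer_oracle()`) is deliberately a different
model class trained under different filters, so it can cross-check designed
sequences for predictor overfitting. Features are $\log_2(1 + \text{count})$
of all 2-6-mers (5,456 features). The pipeline filters the table (minimum
read depth 250; drop sequences containing upstream AUGs; for fixed-end
libraries whose constant region ends in A, drop sequences starting TG, which
would complete an AUG across the junction), fits a Lasso with penalty
0.001 in the $(1/2n)\,\mathrm{RSS} + \alpha\|w\|_1$ parameterization on a
seeded 50,000-sequence subset (glmnet with `standardize = FALSE`, matching
the convention of the reference scikit-learn implementation), keeps the
nonzero-weight features, and refits them by unpenalized least squares
("ridge with zero penalty") on the full training split.
`validate_with_oracle()` reports each design's oracle score and percentile
within a reference pool.

We use $r^2$ to mean the squared Pearson correlation throughout (the
convention used for cross-replicate agreement), not the coefficient of
determination about the identity line; `evaluate_r2()` documents this.

## Design algorithms

**Fast SeqProp** (`fastseqprop_optimize()`) refines a single sequence by
gradient descent on an $L \times 4$ logit matrix. Each iteration centers the
logits per position (a normalization that stabilizes the optimization),
relaxes them through a softmax, draws a discrete one-hot sample on the
forward pass, scores it with the frozen predictor, and passes the
predictor's input gradient straight through the sample to the logits. The
composite loss is the negative predicted MRL (or a squared deviation from a
target MRL) plus sequence penalties: `w_aug` times the AUG count — computed
on the relaxation as the differentiable expected motif count
$\sum_p \prod_j P(\text{base}_j \text{ at } p+j)$, which equals the exact
count on discrete inputs — plus, for fixed-end designs only, an indicator
for an initial TG dinucleotide (the constant region ends in A), plus an
optional VAE margin penalty. Because the forward pass samples, the final
iterate is noisy; the reported design is the lowest-total-loss discrete
sequence seen anywhere in the trace, and the best-so-far trace is monotone
by construction. Recommended iteration counts are 20,000 without VAE
regularization and 5,000 with it; the toy problems in the tests converge
within 2,000. The optimizer is Adam at rate 0.01 (exposed in the
configuration).

**Exploration-network generators** (`den_spec()`, `train_den()`) train a
small dense generator that maps random seed inputs to position logits, with
three loss terms: negative fitness under the frozen predictor, a diversity
penalty equal to the mean pairwise cosine similarity between the relaxed
matrices of co-sampled outputs, and an optional VAE margin penalty. Two
implementation choices matter and were made on numerical grounds:

- *Relaxed fitness with an entropy sharpening ramp.* Fitness (and the VAE
  term) is evaluated on the softmax probabilities rather than on
  straight-through samples, giving exact low-variance gradients; a mean
  per-position entropy penalty, ramped linearly over the first half of
  training, then drives the relaxation toward one-hot vertices so that
  discretely sampled outputs score like the relaxations they came from.
  With straight-through sampling alone, inverse-regression conditioning
  failed to converge to the requested targets at these model sizes.
- *A dense generator.* The outputs are 25-50 nt; a two-hidden-layer MLP
  (widths configurable) conditions and trains more reliably at this scale
  than a transposed-convolution stack, and nothing in the objective needs
  translation equivariance in the generator itself.

In inverse-regression mode the generator receives the target MRL as an
extra input; a bare scalar conditions weakly, so the target enters as a
scaled cubic feature map $(t, t^2, t^3)$, and training draws targets
uniformly from the configured range (default 1.5-7). The learning rate is
cut to 30% for the final quarter of training. Generation samples one
discrete sequence per seed input, scores the batch, sorts by predicted MRL,
and `select_from_top()` reproduces the "pick k at random from the top K"
selection step with a seed.

**The VAE regularizer** (`vae_spec()`, `train_vae()`) learns the marginal
distribution of high-MRL, high-coverage training sequences (coverage filter
then random draws of 5,000 train / 1,000 test from the top 10,000 by MRL)
and scores any sequence's log-likelihood. The estimator is the single-sample
ELBO by default — a lower bound standing in for the likelihood, the standard
surrogate — with an importance-weighted estimator (`n_samples = K`)
available; the importance-weighted bound is tighter on average, which the
tests check statistically. All likelihoods are natural-log; the design
margins (-30 for fixed-end 50nt, -15.6 for 25nt, with loss weights 0.2 and
0.4) are interpreted in the same base. Design losses pass the estimate
through the hinge `margin_penalty()`, `max(0, margin - log p)`: designs
inside the training manifold pay nothing, and the penalty grows linearly
with the likelihood shortfall, absorbing the bias of the ELBO surrogate.

## Kinetics and editing analyses

Decay experiments spike every sample with five control mRNAs at relative
concentrations 1 to 10,000. Spanning four decades, the calibration is only
sensible on logs, so `fit_spikein_calibration()` fits
$\log_{10}(\text{concentration}) \sim \log_{10}(\text{count})$ per
timepoint and maps counts to abundances relative to the top control.
`normalize_series()` then divides by the variant's share of the
untransfected input library to correct initial loading. The 30-minute
timepoint is treated as $t = 0.5$ h. Protein output is proxied by the
integral of mRNA abundance over the observed window (trapezoid rule from
the first to the last timepoint, no extrapolation to $t = 0$), because
under first-order production, protein made is proportional to
$\int \mathrm{mRNA}\,dt$. `fit_single_exponential()` fits
$A e^{-kt}$ by Levenberg-Marquardt with log-linear initialization and
reports the RMSE as a misfit diagnostic — genuinely biphasic decay leaves a
residual an order of magnitude above the single-phase floor.

Editing efficiency consumes an already-aligned amplicon read table
(alignment is out of scope; a thin SAM reader derives indel intervals from
CIGAR strings, anchoring insertions at their reference position). The
statistic is the percentage of reads whose indels touch the 10-base
half-open window $[b - 5, b + 5)$ around the expected breakpoint $b$, among
reads with MAPQ above 20 and mean quality above 30. `kozak_normalize()`
divides each measurement by the strong-Kozak control at the same dosage and
replicate and summarizes per 5'UTR with mean, SD and $n$ across retained
points; excluded points (e.g. failed low-dose transfections) come from an
explicit exclusion table, never from automatic outlier detection.

## The synthetic test bed

Every pipeline is testable without external data through a planted
ground-truth model (`ground_truth_params()`) chosen once to echo the known
qualitative biology:

- baseline MRL `mu0 = 5.5` for a motif-free sequence, typical of a library
  median with eight polysome fractions;
- upstream AUG penalties that plateau at 2.8 MRL units out of frame and
  1.0 in frame, both attenuated exponentially (length scale 6 nt) near the
  5' cap — uAUG repression is large, frame-dependent, and weaker very close
  to the cap, where the scanning machinery has not fully engaged;
- a small bonus of 0.25 MRL units for a 5-nt C/T tract at the cap, decaying
  with distance (length scale 10 nt) — the oligopyrimidine effect is real
  but an order of magnitude smaller than uAUG repression;
- Gaussian observation noise with SD 0.3 MRL units, roughly matching the
  residual spread between noisy replicate measurements;
- a logistic link from MRL to the ribosome-free probability, so that
  poorly initiated variants accumulate in the free fraction.

These values also make the inverse-regression design targets 2-6.5
reachable within the model's dynamic range. They were fixed before the
acceptance harnesses were run and are not tuned.

Fraction counts are simulated by giving each variant a truncated-Poisson
occupancy over loads 1..8 whose conditional mean equals its planted MRL
(the single parameter is found by bisection to 1e-9), plus the free
fraction from the logistic link, and drawing multinomial reads per fraction.
One structural choice deserves emphasis: the fraction-share normalization in
the MRL formula divides by each fraction's total mass, so the formula is an
exactly consistent estimator of the planted conditional mean only when
every fraction carries equal expected sequencing mass. The generator
therefore balances the per-variant input representation (a multiplicative
KL-projection iteration) to equalize expected fraction masses. Real
libraries are not balanced this way, and measured MRL is correspondingly a
proxy rather than an unbiased occupancy mean; the balanced generator is
what makes "recovered MRL equals planted MRL" a well-posed test of the
pipeline code.

Read simulation expands each molecule into duplicated reads (geometric
duplication), injects UMI and adapter errors, and draws quality scores
around the filter threshold. Molecular UMIs within a (variant, fraction)
group are drawn pairwise Hamming distance at least 2 apart so that
zero-error simulations collapse back to exactly the generating counts; real
UMI collisions would cause slight undercounting that the directional
clusterer absorbs, and are deliberately not emulated. Decay simulation
draws Poisson counts around biphasic expectations with per-timepoint depth
jitter and an optional power distortion of the count scale, which the
log-log spike-in calibration inverts exactly.

What passing tests show — and what they do not: the synthetic model is
additive, local, and noise-Gaussian. Success on it demonstrates that the
processing formulas are implemented correctly, that the predictors can
learn planted sequence-function maps of realistic shape and size, and that
the design loop optimizes what it claims to optimize. It does not
demonstrate accuracy on real polysome-profiling data, where effects
interact, noise is heteroskedastic, and secondary structure and
trans-factors matter.

## Problem sizes and numerical choices

The shipped harnesses use desk-scale sizes chosen as the package's own
test conditions: 30,000 sequences for the convolutional predictor
(held-out $r^2 \ge 0.7$ against noisy planted targets; typical runs reach
about 0.85-0.9), 50,000 for the linear-model recovery checks, batches of 64
for generator diagnostics, 100 variants at $10^7$ reads for the MRL
round trip, and 1,000 random matrices for the formula-equivalence check.
Degenerate inputs are handled explicitly: zero-variance vectors refuse a
correlation, empty fraction totals name the offending fraction, an empty
Lasso support suggests lowering the penalty, and non-finite losses abort
training with the epoch or iteration index. Ties are broken
deterministically everywhere (variant id in splits, lexicographic UMIs in
clustering, first-index argmax in decoding), and every stochastic routine
takes an explicit seed.

## Known limitations

- The neural models are intentionally small; they are reference
  implementations tuned for reproducibility on one CPU, not for
  state-of-the-art accuracy on real MPRA data.
- The ELBO understates the true likelihood; margins absorb the bias, but
  absolute likelihood values should not be compared across differently
  trained VAEs.
- The UMI clusterer merges at Hamming distance 1 only; heavily
  error-laden UMIs (distance 2 or more) split clusters and inflate counts.
- The kinetic model diagnoses single-exponential misfit but does not fit a
  mechanistic biphasic model; the integrated abundance is the stability
  summary.
- The editing analysis starts from aligned reads; alignment choices
  (soft-clipping, gap penalties) upstream of the table affect the
  statistic and are outside the package.
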