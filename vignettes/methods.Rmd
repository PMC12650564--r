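---
title: "Methods: autoencoder-compressed genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoencoder-compressed genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Whole-genome sequencing yields genotype matrices with millions of SNP
columns for at most a few hundred to a few thousand individuals. GBLUP
handles this scale because its computations go through the n x n genomic
relationship matrix, but Bayesian whole-genome regression (which samples
every marker effect every MCMC cycle) and machine-learning regressors
(which cross-validate over hyperparameter grids) do not. `gsae`
implements the workaround of compressing the genotype matrix first: the
one-hot-encoded genotypes are split into column chunks, one small
symmetric autoencoder is trained per chunk, and the concatenated
bottleneck activations become a low-dimensional feature matrix on which
any predictor is affordable.

# Compression model

Each dosage g in {0, 1, 2} is one-hot encoded ([1,0,0], [0,1,0],
[0,0,1]), so a chunk of m SNPs enters its autoencoder as a 3m-wide 0/1
row per individual. The network is symmetric: encoder widths
(w1, ..., wk) with ReLU activations, a sigmoid bottleneck of width wk,
and a mirrored sigmoid decoder back to 3m. The loss is the elementwise
mean squared reconstruction error, minimized by Adam on shuffled
minibatches. Design choices worth stating:

* **MSE convention.** The reconstruction error is averaged over *all*
  matrix elements (individuals x features), the convention of standard
  MSE losses. Averaging only over individuals differs by the constant
  feature count and changes nothing about the optimum.
* **Decoder activations.** "Sigmoid for the middle and decoder layers" is
  read literally: every decoder layer is sigmoid, not just the output.
  Sigmoid outputs also guarantee bottleneck features in (0, 1).
* **Optimizer.** Adam with learning rate 1e-3 (a default, the source of
  the architecture table being silent on the optimizer), batch size 32,
  200 epochs; no early stopping, since epoch counts are part of the
  stated configurations.
* **Splits and seeding.** Rows are split 60/20/20
  (training/testing/validation) by one seeded shuffle reused across
  chunks, so partitions are consistent. Weight initialization and
  shuffling are seeded per (run seed, chunk index); chunk results are
  therefore independent of the order in which chunks are trained, and a
  whole run is bit-reproducible on one platform.
* **Chunking.** Chunks are contiguous column blocks in input order,
  `floor(m/k)` SNPs each with the remainder appended to the last chunk.
  Contiguity keeps markers in local linkage disequilibrium together,
  which is what makes a narrow bottleneck per chunk sufficient.
* **Compressed dimension.** d = bottleneck x n_chunks. This per-chunk
  reading reproduces the published architecture table arithmetically in
  all fifteen rows (e.g. bottleneck 5 x 10,000 chunk files = 50,000
  features), and is the interpretation adopted throughout.

`compression_ratio(p, d) = (1 - d/p) * 100`, reported to two decimals.

# Relationship matrices and GBLUP

For raw dosages the VanRaden matrix is `G = WW' / sum(2 p q)` with W the
dosage matrix centered by twice the alt-allele frequency, frequencies
taken from the full genotyped set. For compressed features, columns are
standardized (sample variance, n-1; a population-variance flag exists)
and `G = XX' / ncol(X)`. If the smallest eigenvalue is below -1e-8, 1e-6
is added to the diagonal and logged; compressed matrices can be
near-singular.

Variance components for `y = Xb + a + e`, `a ~ N(0, G sigma_a2)`, are
estimated by REML, profiling the restricted likelihood over the ratio
`lambda = sigma_a2/sigma_e2` on the eigenbasis of G — exact and O(n) per
evaluation after one eigendecomposition. When G is proportional to the
identity the restricted likelihood is flat in lambda; this is detected
on a coarse grid and warned about rather than silently "converging".
GBLUP solves the mixed-model equations in the equivalent variance-model
form (`V = sigma_a2 G_oo + sigma_e2 I` on observed individuals), which
sidesteps inverting G and gives masked individuals their GEBVs through
`G[, obs]`. The model-equation display in the source publication prints
the same symbol X for both incidence matrices; the breeding-value
incidence is taken to be the identity (Z), treating the duplication as a
typo.

The primary correctness oracle is the classical equivalence: GBLUP GEBVs
from VanRaden G must equal ridge-regression SNP-BLUP predictions with
penalty `sigma_e2 / (sigma_a2 / sum(2pq))`, and do so to 1e-6 in the
acceptance suite.

# Bayesian samplers

All four samplers are single-site Gibbs on `y = 1 mu + W beta + e` with
column-centered features and a flat intercept prior:

* **BayesA**: per-marker scaled-inverse-chi-square effect variances
  (df nu = 4.2).
* **BayesB**: spike-and-slab with fixed null proportion pi (default
  0.99). The indicator is drawn from the *marginalized* conditional with
  the effect integrated out, which mixes far better than joint
  Metropolis moves at pi near 1.
* **BayesCpi**: common slab variance; pi sampled from
  `Beta(1 + d - k, 1 + k)`.
* **Bayesian Lasso**: Park–Casella hierarchy; 1/tau_j^2 inverse-Gaussian,
  lambda^2 Gamma-updated (or fixed via configuration).

Prior scales are the conventional heuristic: the scaled-inverse-chi-square
scale is set so the prior mean effect variance equals
`var(y) R2 / (MSx d (1 - pi))` with R2 = 0.5 and MSx the mean column sum
of squares; the exact hyperpriors of the reference implementation are
unpublished, so these defaults are our own and all are exposed in
`bayes_config()` (including direct `scale`/`scale_e` overrides, which the
conjugate-oracle tests use to pin variances). Chains default to 18,000
cycles with 3,000 burn-in. Features are centered but not standardized by
default: compressed features already share the (0,1) scale.

One genuine identifiability caveat, found empirically and worth knowing:
on data with *no* signal, BayesCpi's pi and slab variance are only
jointly identified (the posterior has a ridge where `(1-pi) sigma_b2` is
near zero), so the marginal posterior mean of pi hovers near 0.8 rather
than 1. The identified quantity — the variance fraction attributed to
markers — does go to ~0, and that is what the tests assert.

# Machine-learning regressors

SVR, random forest, kernel ridge regression and gradient-boosted trees
are exposed behind one `fit_predict()` harness: every grid point is
scored by inner 5-fold cross-validation *on the training fold only*
(Pearson correlation by default, matching the accuracy criterion; MSE by
flag), the winner is refit on the full training fold. Because no R
implementations of these learners are available in the supported
dependency set, they are implemented natively: KRR in closed form, SVR
by solving its dual QP with `quadprog`, RF and boosting on a compiled
exact-greedy regression tree with per-split feature subsampling drawn
from R's RNG (so `set.seed()` reproduces forests exactly). Default grids
are small and documented in `default_grids()`; the reference study did
not publish its grids.

# Evaluation

`accuracy = cor(y, GEBV)`; `bias = |1 - cov(y, GEBV)/var(GEBV)|` (the
dispersion regression deviation from 1); MSE and MAE on the validation
fold. The scheme is 20 repeats of 5-fold cross-validation with simple
seeded randomization per repeat. Metrics are computed per fold and then
averaged — the common reporting convention — and pooled values over
concatenated validation sets are also emitted, since the convention
choice is not documented in the source. For GBLUP, "training" masks
validation phenotypes inside the mixed-model equations while all
genotypes stay in G (consistent with the joint model; a refit flag
re-estimates variance components per fold, which is also the default
behavior); Bayes and ML predictors never see validation rows at all.

# The synthetic-data generator

`simulate_genotypes()` draws allele frequencies from U(0.05, 0.5) and
builds haplotypes with a first-order copying chain: the allele at marker
j copies marker j-1's allele on the same haplotype with probability
`ld_rho`, else is drawn fresh. LD therefore decays geometrically —
enough to exercise chunked compression, not a coalescent model.
`simulate_families()` mates two chain-drawn parents per full-sib family
with per-interval recombination probability `(1 - ld_rho)/2`.
`simulate_phenotypes()` picks QTL uniformly, gives them normal effects
(a gamma option provides major-gene architectures), and scales an
orthogonalized residual so the realized sample heritability equals the
target *exactly*, which makes parameter-recovery tests sharp.

What a green test does establish: the pipeline's algebra, seeding, and
statistical behavior under a known additive truth. What it does not:
performance on real LD structure, rare variants, structural variation,
genotyping error, or non-additive architecture — none of which the
generator emulates.

## Why the compression-fidelity check uses families

The headline fidelity property — the correlation between upper-triangle
elements of the compressed-feature G and the VanRaden G exceeding 0.9 at
10-fold compression — is checked on a panel with 26 full-sib families,
mirroring the family-structured populations on which the >0.96 reference
correlations were measured. This is not a convenience: with unrelated
individuals the off-diagonal relationship entries are noise-scale, and
the one-hot (genotype-match) kernel differs from the VanRaden
(dosage-covariance) kernel enough that even *lossless* one-hot features
cap the correlation near 0.82 on an unrelated n=300, m=6000 panel
(measured). Family structure gives the off-diagonals real signal (sibs
~0.5, non-sibs ~0), and both kernels agree on it; the measured
correlation after autoencoder compression to d = 600 is then ~0.94.

# Numerical choices and degenerate inputs

* QC boundaries are strict: a marker is removed only if call rate < 0.90
  or MAF < 0.05 or HWE p < 1e-7; a marker failing several filters counts
  against the first in that order. HWE is the 1-df chi-square test on
  all individuals (monomorphic markers: statistic 0, p 1).
* Missing dosages are `NA`; encoding refuses incomplete matrices and
  names the offending cell. `impute_mean()` exists but is never applied
  implicitly (real pipelines impute upstream).
* One-hot decoding is argmax per triple; an exact tie breaks to the
  lower dosage with a warning.
* `compare_g()` uses the strictly-upper triangle by default (including
  the diagonal inflates agreement); a flag includes it.
* All stochastic stages consume R's RNG only, and the pipeline fans one
  global seed out to stage seeds by fixed offsets recorded in the run
  manifest, so end-to-end reruns are byte-identical.

# Known limitations

* Desk-scale only: the autoencoder trains on thousands, not millions, of
  markers per run; the architecture is dense and CPU-bound.
* Single-trait, additive models; no dominance/epistasis kinships, no
  multi-trait GBLUP, no single-step H-matrix.
* The Bayesian samplers are not meant for uncompressed sequence-width
  matrices — that is the point of compressing first.
* VCF input takes hard GT calls of biallelic records only; multi-allelic
  records are skipped, not decomposed.
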