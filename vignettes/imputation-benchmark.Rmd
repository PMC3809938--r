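---
title: "Benchmarking missing-value imputation on MAQC-style expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation on MAQC-style expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputebench)
```

## The study design

`imputebench` implements a complete evaluation pipeline for missing-value
imputation on Affymetrix-style expression data, organized around the MAQC
reference design: two reference RNA profiles (UHRR and HBRR), four pools
that are physical linear mixtures of the two (A = 100% UHRR, B = 100%
HBRR, C = 75/25, D = 25/75), six laboratory sites, and five replicate
arrays per site-by-pool cell. Because each site-by-pool cell consists of
technical replicates of one RNA pool, the data carry essentially no
biological variability, which is what makes them a clean substrate for
studying imputation error.

The pipeline runs, per site-by-pool cell:

1. **Detection calls.** Per probe pair, the discrimination score
   $(PM - MM)/(PM + MM)$; per probe set and array, a one-sided exact
   Wilcoxon signed-rank test of whether the median score exceeds
   $\tau = 0.015$. A probe set is Present when $p < \alpha_1 = 0.04$,
   Marginal when $\alpha_1 \le p < \alpha_2 = 0.06$, Absent otherwise.
2. **Filtering.** Probe sets Present in *all* replicates of the cell are
   retained; everything else is removed, producing a complete matrix with
   no genuinely missing cells, so that later deletions have known truth.
3. **Summarization.** Ideal-mismatch correction, one-step Tukey-biweight
   summarization of $\log_2(PM - IM)$, and trimmed-mean scale
   normalization to a target intensity of 500.
4. **Deletion and imputation.** A fraction (5% or 10%) of cells is deleted
   uniformly at random; ten imputation configurations (ROW, KNN with
   k = 1 and 5, SVD, LSA, LLS with k = 1, 3, 4, BPCA, NIPALS) fill them
   back in.
5. **Scoring and ranking.** Four error measures per simulation — RMSE,
   LRMSE (RMSE of logs), RAE (absolute error relative to
   $\max(|y|, \epsilon)$, $\epsilon = 0.2$), and RAE-L2 (squared error
   over the true value) — averaged over simulations, ranked across
   methods per metric and cell, then averaged over sites within pools and
   over pools.

All ten imputation engines are implemented in this package behind one
dispatch surface, `impute()`, with a shared contract: observed entries are
returned bit-for-bit unchanged and the output is complete.

## The exact detection test

With 11–20 probe pairs per probe set, the signed-rank null distribution is
computed exactly rather than by normal approximation: the distribution of
the positive-rank sum over all $2^n$ sign assignments is built by a
shift-convolution over the (doubled, so midranks stay integral) ranks.
Zero differences are dropped; tied magnitudes receive midranks. The test
suite cross-checks this against literal enumeration of all sign vectors
for $n \le 12$.

Two conventions worth noting. First, the test is the one-sample
signed-rank test of the median against $\tau$; the hypothesis structure
(a probe set's own scores against a constant) admits no two-sample
rank-sum formulation. Second, saturation handling of the original chip
software is not implemented: the generator produces no saturated probes.

## The synthetic-data generator

No public generative model exists for this design, so the generator's
distributional choices are stand-ins, chosen once on realism grounds and
exposed in `generator_config()` rather than asserted as facts.

**Probe level** (`generate_dataset()`): latent linear-scale expression per
probe set is drawn log-normally for each reference (zero for unexpressed
transcripts), pools mix the two references linearly *before* noise —
pools are physical RNA mixtures — and each measurement receives
multiplicative site, array, and replicate factors plus an additive-free
background term. Probe affinities are log-normal and fixed across arrays,
which is what makes robust summarization meaningful. Expressed fractions
(54% UHRR, 52% HBRR, 50.5% jointly) were set so that downstream percent
present lands in the low-to-high fifties, the plausible range for this
chip family; the joint fraction matters because the mixture pools express
the union of the two references' transcripts.

**Expression level** (`generate_expression_matrix()`): a shortcut
generator for benchmark matrices that emulates the *output* of the
detection-filter-summarize-normalize pipeline on one cell. Its structure
encodes five known properties of technical-replicate array data:

* a handful of systematic per-array technical factors with a decaying
  amplitude spectrum (5 factors, harmonic decay), to which each gene
  responds with its own loading — the reason low-rank methods work on
  arrays at all;
* blocks of near-duplicate probe sets (within-block loading correlation
  0.99, blocks of 100): chips carry multiple probe sets per transcript
  and co-regulated transcripts, and these near-duplicates are what
  correlation-based neighbor selection can genuinely exploit;
* two-component measurement noise — 1% multiplicative plus an additive
  component (sd 12) that makes low-intensity measurements proportionally
  noisy, the standard error model for array intensities;
* a small residual array-scale effect (2%): benchmark deletion happens
  *after* trimmed-mean normalization, which removes most of the scale;
* truncation of the low-intensity tail at 30: detection filtering removes
  unreliably measured transcripts from the complete matrices.

What the generator does **not** emulate: probe-level saturation, spatial
chip artifacts, intensity-dependent affinity biases, and any biological
variability. Tests that pass on this generator therefore say that the
pipeline machinery and the relative behavior of the methods are right
under these structural assumptions; they do not certify error magnitudes
on real chips.

## Numerical choices

* **Tukey biweight** is the documented one-step variant with $c = 5$,
  $\epsilon = 10^{-4}$; the biweight of a constant vector is that
  constant, and a MAD of zero sends outliers' weights to zero.
* **Scale normalization** scales every array to trimmed mean 500
  (2% trim); a flag switches to baseline-array mode. The operation is
  idempotent to floating-point tolerance.
* **SVD imputation** stops when the total absolute change in the matrix
  falls below 0.01 (the expression-scale threshold of the method's
  description); two eigen genes by default. Its per-row regressions use
  a pseudoinverse, so rank-deficient observed sets cannot error.
* **LLS** truncates singular values below 5% of the largest when solving
  the neighbor system: the most-correlated neighbors of expression data
  are near-collinear, and directions at the noise level otherwise
  amplify measurement noise without constraining the fit. With k equal
  to the number of observed columns the untruncated solve is an exact
  interpolation through noise — the truncation is what makes k = 4 with
  five replicates behave.
* **NIPALS and SVD do not center by default.** Positive expression data
  with multiplicative structure is (near) low-rank *uncentered*; a
  per-column observed-mean centering turns an exactly rank-1 matrix into
  a rank-2 one that a single greedy component cannot reproduce, which
  would break exact recovery in the model-matched limit. A `center` flag
  restores conventional behavior.
* **BPCA** is an EM/variational fit of probabilistic PCA with an
  automatic-relevance-determination prior; the latent posterior for an
  incomplete row conditions on its observed coordinates only, so imputed
  cells never feed back into the fit, and a noise-variance floor keeps
  the ARD shrinkage active even on noiseless low-rank data. The
  initialization is the SVD of the row-average-filled matrix plus seeded
  jitter, making runs reproducible.
* **LSA** follows the published outline — weighted univariate regressions
  on correlated genes and on other arrays, mixed by a weight minimizing
  held-out squared error — but the adaptive weighting internals of the
  original Java implementation are not public; this package bins a
  seeded held-out probe set of observed cells by gene-correlation
  strength (quartiles) and fits one closed-form mixing weight per bin.
* **Scoring floor.** Regression methods can predict nonpositive values
  where log-scale errors are undefined; before scoring, estimates are
  floored at half the smallest observed value (configurable), which
  keeps all four measures defined while still penalizing such estimates
  heavily on the log scale.
* **RMSE/LRMSE carry the outer square root** their names imply; RAE-L2 is
  the mean of squared error over the true value, with an optional outer
  root behind a flag.
* **Deletion counts** use round-half-even on `fraction * G * S`; masks are
  uniform over all cells with no row protection — fully-missing rows are
  the imputation methods' problem, handled by a documented fallback chain
  (method, then row average, then global mean).
* **Ranking** uses midranks for ties, which preserves the total rank sum
  $n(n+1)/2$ at every aggregation level; aggregation is sites-within-pool
  first, then pools, which differs from a flat cell mean only in
  unbalanced designs (an `allow_unbalanced` flag exists for such data).
* **Failed simulations** are flagged and excluded from averages rather
  than assigned a worst rank — exclusion is the least distorting default
  when failures are rare, and counts are logged.

## Reproducibility model

Every stochastic step flows from explicit integer seeds: the generator
config seed, per-simulation seeds derived as `xor(master, sim_index)` so a
single simulation can be re-run in isolation, per-method seeds for BPCA
initialization and the LSA probe set, and cell-keyed seeds in
`run_study()` so results do not depend on execution order. A study run
writes a JSON manifest from which `read_manifest()` reconstructs the
configuration; re-running it reproduces every output file bit for bit.

## Problem sizes

The packaged tests and the acceptance script run scaled-down versions of
the study: hundreds rather than tens of thousands of probe sets, two
sites, and 3–100 Monte-Carlo simulations rather than 1000. These sizes
were chosen so a full check completes in minutes on one core while the
quantities of interest — exactness of the statistics, call rates,
rank orderings — are already stable at that scale. The benchmark that
compares all ten methods runs at the full per-cell matrix size
(2000 retained probe sets by 5 replicates, 100 simulations).

## Known limitations

* The spatial zone-based background step of the original preprocessing is
  omitted; the generator carries its background in the noise-floor term,
  and no chip geometry exists to feed such a step.
* Method positions for the configurations the directional check does not
  pin (ROW, NIPALS, BPCA, LSA) vary with the generator's noise regime;
  only the stable inequalities (single-neighbor KNN worst; LLS with
  k = 4 ahead of KNN and SVD) should be read as reproductions.
* Marginal calls are simply removed by the filter; no downstream handling
  of Marginal probe sets is implemented.
* The error measures are purely numerical; nothing here speaks to the
  effect of imputation on downstream biological analyses.
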