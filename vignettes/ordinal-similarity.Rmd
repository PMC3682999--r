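---
title: "Ordinal similarity structures: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal similarity structures: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordsim)
```

## The problem

When listeners process spoken sentences, can the relations between the
words they hear — which words are semantically close, which far — be
recovered from their neural activity?  `ordsim` implements a
representational comparison that answers this at the *ordinal* level.
Rather than asking whether a decoder predicts words accurately, it asks
whether the *pattern of confusions* the decoder makes carries the same
similarity structure as a semantic model such as WordNet or a latent
semantic analysis (LSA) space.

The data are single-trial epochs from a multichannel recording (in the
motivating setting, 15-channel EEG at an effective 62.5 Hz, time-locked
to words inside sentences about European geography).  The semantic side
is any real-valued word-by-word similarity matrix.

## The procedure

1. **Epochs.** Each word occurrence contributes one sample starting 10
   data points (160 ms at 62.5 Hz) after word onset.  Every event is
   extended by 50 points (~800 ms, covering the N400 window) and the
   common length is the floor of the mean extended duration over all
   events, so all samples are equal length.  Channels are concatenated
   into one feature vector.
2. **Classification.** A linear discriminant with a nested
   principal-component reduction is run in a stratified 5-fold
   cross-validation loop; the true-versus-predicted counts over all
   folds form a confusion matrix `M = (m_ij)`.  Row-normalizing gives
   conditional probability estimates `p_ij` that a sample from word i
   is classified as word j.
3. **Orders.** For each focus word `w`, the row `p_w.` induces a strict
   partial order: word `a` sits above word `b` when `a` is strictly more
   similar to `w` (larger `p_wa`); ties are incomparable.  The order is
   stored as a binary connection matrix, `conn[i, j] = 1` iff word `j`
   is strictly more similar to the focus than word `i`.  The same
   construction applied to the semantic matrix gives a second family of
   N orders.
4. **Invariants.** Each order is unfolded into its maximal chains — one
   representative per tie group, so the number of chains is the product
   of tie-group sizes.  The orders invariant between the brain-derived
   and model-derived structures are the maximal-length common
   subsequences over all pairs of chains; equivalently, chains of the
   element-wise intersection of the two connection matrices.
5. **Significance and counting.** The tie-aware Spearman correlation of
   the two underlying rows is compared with the critical value of the
   exact permutation null (0.6485 at N = 10 under the two-sided 0.05
   convention).  Over `n_boot` bootstrap re-classifications, the count
   of (repetition, word) pairs whose invariant order is significant —
   at most `n_boot * N` — measures the structural similarity between
   the recording and the semantic model.  Two models can then be
   compared by their counts on the same recordings.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `offset_samples` | 10 | epoch start shift; 160 ms at 62.5 Hz |
| `extension_samples` | 50 | epoch extension; ~800 ms at 62.5 Hz |
| `folds` | 5 | cross-validation folds, stratified per word |
| `pca_variance` | 0.95 | training-variance fraction kept by the nested PCA |
| `shrinkage` | automatic | pooled-covariance shrinkage toward a scaled identity (Ledoit-Wolf-style); 0 disables |
| `n_boot` | 60 | bootstrap re-classifications per recording |
| `alpha` | 0.05 | two-sided significance level for the exact null |
| `tie_decimals` | none | optional rounding before tie detection |

The referenced decoding literature does not fully specify its
classifier internals (e.g. the exact component-selection rule), so the
classifier here is a documented stand-in that preserves the stated
structure — linear discriminant, nested PCA, stratified 5-fold CV.  The
downstream ordinal machinery is classifier-agnostic: any procedure that
yields confusion matrices can feed it.

## Numerical choices

* **Ties.** Equality is exact (tolerance 1e-12) unless `tie_decimals`
  is set; rounding reproduces printed tables, where 0.00 and 0.000 tie.
* **Epoch length** uses `floor` of the mean extended duration: indices
  must be integers and the bias is under one sample.  The mean is taken
  over all events, not per word.  Epochs overrunning the recording are
  an error, never padded: padding would silently change feature
  statistics.
* **Maximal chains, not all topological sorts.**  Orderings of a
  connection graph can be read either as full topological sorts (every
  node appears) or as maximal chains (tied nodes split across chains).
  The printed worked example lists nine-element sequences for a ten-word
  set with one tie, which is the maximal-chain reading; that is what is
  implemented.  Chains are enumerated as source-to-sink paths of the
  transitive reduction, which for finite posets is exactly the set of
  maximal chains.
* **Significance convention.**  The exact enumeration of all `n!` rank
  permutations at n = 10 gives a 0.025 upper-tail critical value of
  0.6485 (to four decimals) — the printed threshold is recovered only
  under the two-sided reading of "p < 0.05" (one-sided would give
  0.5636), so the two-sided convention is adopted throughout.  The
  enumeration uses the generating-function (permanent) form of the
  distribution of the rank-difference sum, which is exact and takes
  about a second at n = 10; brute-force enumeration is kept as a test
  oracle up to n = 8.  At n = 3 no value reaches the 0.025 tail
  (minimum attainable tail is 1/6), which the function signals as
  unattainable rather than returning a misleading number.
* **Undefined correlations.**  A constant row (a word never confused
  with anything at varying rates) has no ordinal information; its
  correlation is undefined and it is counted as not significant.
* **Significance reading.**  Whether a "significant invariant partial
  order" additionally requires a non-trivial invariant (length >= 2) is
  ambiguous; the correlation-only reading is used because it yields the
  stated maximum count of 300 for 30 classifications of 10 words.
* **Counting unit.**  One potential significant invariant per word per
  repetition, never more, matching the 300 cap above.
* **Clustering distance.**  Similarity trees use complete linkage on
  `max(s) - s` (diagonal excluded from the maximum); `1 - s` is
  available for matrices already scaled to [0, 1].  The choice of
  transform is a convention, not part of the method's claims.
* **Bootstrap.**  Resampling is with replacement *within* each word
  class, keeping row denominators fixed so every word's conditional
  probabilities remain estimable in every repetition.

## The synthetic generator

Recorded EEG for the motivating experiments is not publicly deposited,
so the package ships a generator that emulates exactly the statistical
structure the method consumes — and nothing more.  Per-word prototype
vectors are constructed whose pairwise inner products reproduce a
min-max-scaled target similarity matrix (via eigendecomposition used as
a Gram factorization; negative eigenvalues are clipped at zero with a
warning, tolerance 1e-8, since arbitrary similarity matrices need not
be positive semi-definite).  Each trial is `snr * prototype` plus unit
Gaussian noise at every channel-sample, laid into a signal matrix so
that `extract_epochs()` recovers the exact prototype window.  Defaults
mirror the recorded design: 15 channels, 62.5 Hz, the printed per-word
trial counts (640 trials for the first word set), and `snr = 2.1`,
which puts cross-validated single-trial accuracy in the mid-20s percent
range — the regime the method operates in.

What the generator does **not** emulate: EEG spectra (noise is white),
volume conduction and channel correlation, ocular or movement
artifacts, latency jitter, word-length differences (all simulated
epochs are equal length by construction), and any dependence between
trials.  Passing the end-to-end tests therefore shows the *pipeline*
recovers planted ordinal structure at realistic accuracy levels; it is
not evidence about any property of real recordings.

The WordNet-style target used in examples and tests
(`synthetic_geography_similarity()`) is a hand-constructed block
matrix over the geography words (cities / countries / directions, with
capital-country pairs boosted); the published similarity matrices exist
only as heat maps, so this stand-in is clearly labelled synthetic.

## Problem sizes used by the tests

End-to-end tests run a scaled configuration chosen to exercise every
stage in minutes on one CPU: 6 channels, 20-sample epochs (offset 4,
extension 10), 30 trials per word, `snr = 1.6` — which reproduces the
~25% accuracy regime at this scale — with 12 bootstrap repetitions and
20 generator seeds for the recovery property (the true generating
similarity matrix must beat a word-permuted decoy on the significant
invariant count in at least 95% of replicates).  Oracle comparisons use
exhaustive enumeration: all rank permutations up to n = 8 for the
critical value, and all subsequences of all chains up to 7 words for
the invariant machinery.

## Known limitations

* The classifier is a faithful stand-in, not a reimplementation of the
  referenced proprietary pipeline; absolute accuracies on real data
  will differ.  No artifact removal, filtering or re-referencing is
  provided; real recordings must be pre-cleaned.
* Semantic similarity matrices are inputs.  Only the combination step
  (averaging, optionally after min-max scaling) is implemented for
  WordNet-style measure stacks; computing the individual graph-based
  measures would require a lexical-database dependency outside this
  package's scope.  The LSA implementation is a small, exact
  truncated-SVD term-space model suitable for modest corpora, not a
  web-scale system.
* Semiorders and interval orders (thresholded tie handling) are not
  implemented; ties are exact incomparabilities.
* Reported per-participant counts from the motivating experiments
  depend on undeposited recordings and are not reproducible here; the
  package instead verifies every printed worked-example quantity and
  the method's internal laws.

## A worked example

```{r worked-example}
fx <- geography_fixtures()
brain <- build_connection_matrix(fx$table1$brain, "London")
lang <- build_connection_matrix(fx$table1$language, "London")
maximal_chains(brain)
maximal_chains(lang)
maximal_common_subsequences(brain, lang)
spearman_rho(fx$table1$brain, fx$table1$language)
exact_critical_rho(10, 0.05)
```
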