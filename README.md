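# ordsim

Ordinal similarity structures for comparing neural decoding data with
semantic models.

## What it does

Single-trial decoding of words from multichannel recordings (e.g.
15-channel EEG at an effective 62.5 Hz, time-locked to words in spoken
sentences) is noisy: accuracies in the 20–30% range for 10 words are
typical.  `ordsim` extracts structure from exactly that noise.  The
*pattern of confusions* a classifier makes — which words it mistakes
for which — estimates conditional probabilities `p_ij = P(predicted
ω_j | true ω_i)`, and each row of that matrix induces, for its focus
word ω, a strict partial order of similarity differences: ω_a sits
above ω_b when ω_a is strictly more similar to ω (ties are
incomparable).  The same construction applied to a semantic similarity
matrix — a combined WordNet measure, or an LSA term space — yields a
second family of N orders.

The structural similarity between brain and model is then measured
ordinally:

* each order is unfolded into its **maximal chains** (one
  representative per tie group);
* the **invariant partial orders** are the maximal-length common
  subsequences over all pairs of brain/model chains — equivalently,
  chains of the element-wise intersection `R^INV = R^B ∩ R^P` of the
  two connection matrices;
* an invariant order is **significant** when the Spearman rank
  correlation of its two source rows reaches the critical value of the
  exact permutation null (ρ = 0.6485 at N = 10, two-sided 0.05);
* over `n_boot` bootstrap re-classifications, the **count** of
  significant invariant orders (at most `n_boot × N`) measures the
  strength of the structural similarity, and lets two semantic models
  be ranked against the same recordings.

The package provides the full pipeline — epoch extraction, a
PCA-plus-shrinkage-LDA classifier in stratified cross-validation,
bootstrap repetition, the ordinal machinery, exact critical values,
complete-linkage similarity trees, a small LSA implementation, and a
synthetic-trial generator with known ground truth — plus an `ordsim`
command-line tool (under `exec/`) for shell pipelines.

## Worked example

The bundled fixtures carry the published per-word values for *London*
against the word set {London, Moscow, Paris, north, south, east, west,
Germany, Poland, Russia}: the combined-WordNet similarities
(`language`) and conditional probability estimates from one
single-trial EEG classification (`brain`).

```r
library(ordsim)
fx <- geography_fixtures()
brain <- build_connection_matrix(fx$table1$brain, "London")
lang  <- build_connection_matrix(fx$table1$language, "London")
maximal_chains(brain)
#> Chain set for focus 'London': 2 maximal chain(s)
#>    London > Paris > Moscow > Germany > north > Russia > Poland > east > south
#>    London > Paris > Moscow > Germany > north > Russia > Poland > east > west
maximal_chains(lang)
#> Chain set for focus 'London': 1 maximal chain(s)
#>    London > Paris > Moscow > Germany > Russia > Poland > north > south > west > east
maximal_common_subsequences(brain, lang)
#> Invariant orders for focus 'London': 3 chain(s) of length 7
#>    London > Paris > Moscow > Germany > Russia > Poland > south
#>    London > Paris > Moscow > Germany > Russia > Poland > east
#>    London > Paris > Moscow > Germany > Russia > Poland > west
spearman_rho(fx$table1$brain, fx$table1$language)
#> [1] 0.9240164
exact_critical_rho(10, 0.05)
#> [1] 0.6484848
```

Reading the output: the brain data yield **two** nine-word chains
(south and west are tied at probability 0), the WordNet data one
ten-word chain, and the structures share **three** invariant chains of
length seven — a shared six-word spine London → Paris → Moscow →
Germany → Russia → Poland branching into south, west and east.  The
rows correlate at ρ = 0.924, above the exact-null critical value
0.6485, so London contributes one significant invariant partial order.

A full synthetic run, from recording to counts:

```r
spec <- generator_spec(seed = 7)          # 640 trials, 15 channels, ~25% accuracy
sim  <- simulate_trials(spec)
ds   <- extract_epochs(sim$recording)
cms  <- bootstrap_classify(ds, classifier_spec(), n_boot = 30, seed = 7)
count_significant(cms, sim$target_sim,
                  significance_config(rho_threshold = 0.6485))
```

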