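Package: ordsim
Title: Ordinal Similarity Structures for Comparing Neural Decoding Data
    with Semantic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures structural similarity between single-trial neural
    decoding data and semantic models at the ordinal level.  Trial epochs
    are classified into word classes with a cross-validated linear
    discriminant (nested principal-component reduction, bootstrap
    repetition); the row-normalized confusion structure yields, for each
    word, a strict partial order of similarity differences.  The same
    orders are derived from semantic similarity matrices (e.g.
    WordNet-combined or latent-semantic-analysis scores).  Orders
    invariant between the two sources are extracted as maximal-length
    common subsequences of their maximal chains, and those whose
    underlying rows correlate at or above the exact permutation-null
    critical value of Spearman's rho are counted; the count measures the
    strength of the structural similarity.  Includes labeled-matrix I/O,
    an exact tie-aware Spearman critical-value computation, complete-
    linkage similarity trees, a small latent-semantic-analysis
    implementation, and a synthetic-trial generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
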