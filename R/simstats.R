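#' Tie-aware Spearman rank correlation
#'
#' Assigns average ranks to ties in each row and computes the Pearson
#' correlation of the two rank vectors from hand-expanded sums.  A
#' constant row has no ordinal information; the correlation is then
#' undefined and `NA_real_` is returned (treated downstream as not
#' significant).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return the correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(10, 30, 50, 70))  # 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("rows have different lengths")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values, got ", n)
  if (anyNA(x) || anyNA(y)) stop("missing values in input rows")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sum(dx * dy) / sqrt(sxx * syy)
}

# Exact counts of the permutation distribution of D = sum (i - p(i))^2
# over all n! untied rank permutations p, via the Ryser permanent of the
# matrix with polynomial entries x^((i-j)^2).  Returns a vector c where
# c[d + 1] is the number of permutations with D = d, d = 0..n(n^2-1)/3.
# Counts fit exactly in doubles for n <= 10 (10! = 3628800).
spearman_d2_distribution <- function(n) {
  stopifnot(n >= 2L, n <= 12L)
  dmax <- n * (n^2 - 1) / 3
  # row products can transiently exceed dmax inside Ryser subsets
  work <- sum(pmax((seq_len(n) - 1L)^2, (n - seq_len(n))^2)) + 1L
  shifts <- (outer(seq_len(n), seq_len(n), "-"))^2  # shifts[i, j]
  total <- numeric(work)
  sign_n <- (-1)^n
  for (s in seq_len(2^n - 1L)) {
    cols <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    prod_poly <- c(1, numeric(work - 1L))
    for (i in seq_len(n)) {
      acc <- numeric(work)
      for (j in cols) {
        sh <- shifts[i, j]
        len <- work - sh
        acc[(sh + 1L):work] <- acc[(sh + 1L):work] + prod_poly[1:len]
      }
      prod_poly <- acc
    }
    total <- total + sign_n * (-1)^length(cols) * prod_poly
  }
  counts <- total[1:(dmax + 1L)]
  counts <- round(counts)
  if (!isTRUE(all.equal(sum(counts), factorial(n)))) {
    stop("internal error: permutation counts do not sum to n!")
  }
  counts
}

#' Exact critical value of Spearman's rho under the permutation null
#'
#' Enumerates the exact null distribution of `rho = 1 - 6 * sum(d^2) /
#' (n * (n^2 - 1))` over all `n!` untied rank permutations and returns
#' the smallest attainable rho whose exact upper-tail probability is at
#' most `alpha / 2` (the two-sided convention; at n = 10, alpha = 0.05
#' this gives 0.6485 to four decimals).  The enumeration is exact for
#' `n <= 10`; beyond that a t-approximation is used with a warning.
#'
#' When no attainable rho reaches the tail bound (e.g. n = 3 at alpha =
#' 0.05, where the smallest tail probability is 1/6), `NA_real_` is
#' returned with a warning: significance is unattainable at that size.
#'
#' @param n number of paired observations (at least 3).
#' @param alpha two-sided significance level in (0, 1).
#' @return the critical rho, or `NA_real_` if unattainable.
#' @export
exact_critical_rho <- function(n, alpha = 0.05) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be at least 3")
  stopifnot(alpha > 0, alpha < 1)
  tail <- alpha / 2
  if (n > 10L) {
    warning("exact enumeration limited to n <= 10; ",
            "using the t-approximation for n = ", n)
    tcrit <- stats::qt(1 - tail, df = n - 2)
    return(tcrit / sqrt(n - 2 + tcrit^2))
  }
  counts <- spearman_d2_distribution(n)
  nfact <- factorial(n)
  cum <- cumsum(counts)  # cum[d + 1] = #permutations with D <= d
  # compare in counts to dodge floating-point edge effects at the boundary
  ok <- which(counts > 0 & cum <= tail * nfact + 1e-7)
  if (!length(ok)) {
    warning("no attainable rho reaches two-sided alpha = ", alpha,
            " at n = ", n)
    return(NA_real_)
  }
  d <- max(ok) - 1L
  1 - 6 * d / (n * (n^2 - 1))
}

#' Significance configuration for invariant-order counting
#'
#' @param alpha two-sided significance level.
#' @param rho_threshold optional fixed critical rho; `NULL` computes it
#'   exactly from the word-set size via [exact_critical_rho()] at first
#'   use.
#' @return list of class `"significance_config"`.
#' @export
significance_config <- function(alpha = 0.05, rho_threshold = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(rho_threshold)) {
    stopifnot(rho_threshold >= -1, rho_threshold <= 1)
  }
  structure(list(alpha = alpha, rho_threshold = rho_threshold),
            class = "significance_config")
}

resolve_rho_threshold <- function(cfg, n) {
  if (!is.null(cfg$rho_threshold)) return(cfg$rho_threshold)
  exact_critical_rho(n, cfg$alpha)
}

#' Assess one word: invariant orders and their significance
#'
#' Builds the brain-derived and semantic-model-derived orders for one
#' focus word from the two value rows, extracts the invariant orders
#' (maximal-length common subsequences of the maximal chains), computes
#' the tie-aware Spearman correlation of the rows, and flags the word as
#' carrying a significant invariant partial order when the correlation
#' reaches the critical threshold.
#'
#' @param brain_row named numeric row of conditional probabilities (or
#'   any similarity-difference values) for the focus word.
#' @param semantic_row named numeric row of semantic similarities,
#'   aligned to the same word set.
#' @param focus the focus word label.
#' @param cfg a [significance_config()].
#' @param tie_decimals see [build_connection_matrix()].
#' @return an object of class `"word_assessment"`: list with `focus`,
#'   `rho`, `significant`, `invariant` (an `invariant_result`), and the
#'   threshold used.
#' @export
assess_word <- function(brain_row, semantic_row, focus,
                        cfg = significance_config(),
                        tie_decimals = NULL) {
  if (!identical(names(brain_row), names(semantic_row))) {
    stop("brain and semantic rows are not aligned to the same word set")
  }
  ob <- build_connection_matrix(brain_row, focus, tie_decimals)
  os <- build_connection_matrix(semantic_row, focus, tie_decimals)
  inv <- maximal_common_subsequences(ob, os)
  rho <- spearman_rho(brain_row, semantic_row)
  thr <- resolve_rho_threshold(cfg, length(brain_row))
  sig <- !is.na(rho) && !is.na(thr) && rho >= thr
  structure(list(focus = focus, rho = rho, significant = sig,
                 invariant = inv, rho_threshold = thr),
            class = "word_assessment")
}

#' Count significant invariant partial orders over bootstrap repetitions
#'
#' For each repetition's confusion matrix: row-normalize, then assess
#' every word against the corresponding row of the semantic similarity
#' matrix.  The total number of (repetition, word) pairs whose invariant
#' order is significant measures the strength of the structural
#' similarity between the decoding data and the semantic model; its
#' maximum is `length(cms) * N` (e.g. 300 for 30 classifications of 10
#' words).
#'
#' @param cms list of [confusion_matrix()] objects over a shared word
#'   set (one per classification repetition).
#' @param sem a [similarity_matrix()]; labels must match the confusion
#'   matrices' word set (rows are permuted into its order).
#' @param cfg a [significance_config()].
#' @param tie_decimals see [build_connection_matrix()].
#' @return an object of class `"structural_similarity_report"`: list
#'   with `assessments` (data frame: repetition, word, rho, significant,
#'   max_length, n_invariant_chains), `total_significant`,
#'   `max_possible`, `rho_threshold`, `words`.
#' @export
count_significant <- function(cms, sem, cfg = significance_config(),
                              tie_decimals = NULL) {
  if (!length(cms)) stop("need at least one confusion matrix")
  words <- word_labels(cms[[1L]])
  sem <- align_to_words(sem, words)
  thr <- resolve_rho_threshold(cfg, length(words))
  cfg_fixed <- significance_config(cfg$alpha, rho_threshold = thr)
  rows <- vector("list", length(cms) * length(words))
  k <- 0L
  for (r in seq_along(cms)) {
    p <- row_normalize(align_to_words(cms[[r]], words))
    for (w in as.character(words)) {
      a <- assess_word(unclass(p)[w, ], unclass(sem)[w, ], w,
                       cfg = cfg_fixed, tie_decimals = tie_decimals)
      k <- k + 1L
      rows[[k]] <- data.frame(
        repetition = r, word = w, rho = a$rho,
        significant = a$significant,
        max_length = a$invariant$max_length,
        n_invariant_chains = length(a$invariant$invariant_chains),
        stringsAsFactors = FALSE)
    }
  }
  assessments <- do.call(rbind, rows)
  structure(list(assessments = assessments,
                 total_significant = sum(assessments$significant),
                 max_possible = length(cms) * length(words),
                 rho_threshold = thr,
                 words = words),
            class = "structural_similarity_report")
}

#' @export
print.structural_similarity_report <- function(x, ...) {
  cat("Structural similarity report:",
      x$total_significant, "of", x$max_possible,
      "significant invariant partial orders",
      sprintf("(rho threshold %.4f)\n", x$rho_threshold))
  invisible(x)
}

#' Complete-linkage similarity tree
#'
#' Converts a similarity matrix into distances and clusters the words by
#' complete (furthest-neighbour) linkage.  The input is symmetrized as
#' `(s + t(s)) / 2`; the distance is `max(s) - s` with the diagonal
#' excluded from the maximum (`distance = "smax"`), or `1 - s` for
#' matrices already scaled to `[0, 1]` (`distance = "one-minus"`).
#'
#' @param sim a [similarity_matrix()].
#' @param distance distance transform, `"smax"` or `"one-minus"`.
#' @return an object of class `"hclust"` (see [stats::hclust()]).
#' @export
cluster_tree <- function(sim, distance = c("smax", "one-minus")) {
  distance <- match.arg(distance)
  m <- unclass(check_square_labeled(sim, what = "similarity matrix"))
  if (nrow(m) < 2L) stop("need at least 2 words to cluster")
  s <- (m + t(m)) / 2
  d <- if (distance == "smax") {
    off <- s; diag(off) <- -Inf
    max(off) - s
  } else {
    1 - s
  }
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Write a dendrogram as a merge table and Newick string
#'
#' @param hc an `"hclust"` tree from [cluster_tree()].
#' @param merge_path optional CSV path for the merge table (merge
#'   indices and heights).
#' @param newick_path optional path for the Newick representation.
#' @return the Newick string, invisibly.
#' @export
write_dendrogram <- function(hc, merge_path = NULL, newick_path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  if (!is.null(merge_path)) {
    utils::write.csv(data.frame(left = hc$merge[, 1L],
                                right = hc$merge[, 2L],
                                height = hc$height),
                     merge_path, row.names = FALSE)
  }
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  invisible(nwk)
}
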