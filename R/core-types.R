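#' Word sets and labeled matrices
#'
#' The unit of analysis is a fixed, ordered set of word labels shared by
#' every matrix in a comparison.  `word_set()` validates a character
#' vector of labels; the three matrix constructors validate and class a
#' square numeric matrix whose rows and columns are indexed by the word
#' set, in its canonical order.
#'
#' @param labels character vector of unique, non-empty word labels
#'   (length at least 2).
#' @return `word_set()` returns a character vector of class `"word_set"`.
#' @examples
#' ws <- word_set(c("London", "Moscow", "Paris"))
#' @export
word_set <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop("a word set needs at least 2 labels, got ", length(labels))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate word labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop("word labels must be non-empty and non-missing")
  }
  structure(labels, class = "word_set")
}

#' @rdname word_set
#' @param x object to test or coerce.
#' @export
is_word_set <- function(x) inherits(x, "word_set")

#' @rdname word_set
#' @export
as_word_set <- function(x) if (is_word_set(x)) x else word_set(x)

check_square_labeled <- function(m, words = NULL, what = "matrix") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop(what, " must be square, got ", nrow(m), "x", ncol(m))
  }
  if (is.null(words)) {
    if (is.null(rownames(m))) stop(what, " needs row/column word labels")
    words <- as_word_set(rownames(m))
  } else {
    words <- as_word_set(words)
    if (nrow(m) != length(words)) {
      stop(what, " dimension ", nrow(m), " does not match word set of size ",
           length(words))
    }
  }
  if (!is.null(colnames(m)) && !identical(colnames(m), as.character(words))) {
    stop(what, " column labels disagree with row labels / word set")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(as.character(words), as.character(words))
  if (any(!is.finite(m))) stop(what, " contains non-finite values")
  m
}

#' @rdname word_set
#' @param counts square matrix of non-negative integer classification
#'   counts; rows index the true class, columns the predicted class.
#' @param words optional word set; defaults to the matrix row names.
#' @export
confusion_matrix <- function(counts, words = NULL) {
  m <- check_square_labeled(counts, words, "confusion matrix")
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9)) {
    stop("confusion counts must be non-negative integers")
  }
  m <- round(m)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @rdname word_set
#' @param probs square matrix of conditional probability estimates; each
#'   row must sum to 1 within 1e-9.
#' @export
cond_prob_matrix <- function(probs, words = NULL) {
  m <- check_square_labeled(probs, words, "conditional probability matrix")
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("conditional probabilities must lie in [0, 1]")
  }
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad)) {
    stop("rows must sum to 1 within 1e-9; offending row(s): ",
         paste(rownames(m)[bad], collapse = ", "))
  }
  structure(m, class = c("cond_prob_matrix", "matrix", "array"))
}

#' @rdname word_set
#' @param sims square matrix of real-valued similarities (no symmetry is
#'   required; rows are consumed independently).
#' @export
similarity_matrix <- function(sims, words = NULL) {
  m <- check_square_labeled(sims, words, "similarity matrix")
  structure(m, class = c("similarity_matrix", "matrix", "array"))
}

#' Extract the word set of a labeled object
#'
#' @param x a labeled matrix, order, chain set, or other ordsim object.
#' @return a [word_set()].
#' @export
word_labels <- function(x) {
  if (is_word_set(x)) return(x)
  if (is.matrix(x)) return(as_word_set(rownames(x)))
  if (is.list(x) && !is.null(x$words)) return(as_word_set(x$words))
  stop("cannot extract word labels from a ", paste(class(x), collapse = "/"))
}

#' Align a labeled matrix to a reference word order
#'
#' Two matrices entering a comparison must carry the same label set; the
#' second is permuted to the first's canonical order.  Mismatched label
#' sets are an error, never silently intersected, because dropping words
#' changes every N-dependent statistic downstream.
#'
#' @param m a labeled square matrix (any of the three matrix classes).
#' @param words the reference [word_set()].
#' @return `m` with rows and columns permuted to `words`, same class.
#' @export
align_to_words <- function(m, words) {
  words <- as_word_set(words)
  have <- rownames(m)
  if (!setequal(have, as.character(words)) ||
      length(have) != length(words)) {
    stop("label sets differ: matrix has {",
         paste(setdiff(have, words), collapse = ", "),
         "} extra and lacks {",
         paste(setdiff(as.character(words), have), collapse = ", "), "}")
  }
  cls <- class(m)
  out <- unclass(m)[as.character(words), as.character(words), drop = FALSE]
  class(out) <- cls
  out
}

#' Row-normalize a confusion matrix into conditional probabilities
#'
#' Converts classification counts into estimates of the conditional
#' probability that a test sample from the row class is predicted as the
#' column class: `p[i, j] = m[i, j] / sum_j m[i, j]`.
#'
#' @param cm a [confusion_matrix()] (or square count matrix with labels).
#' @return a [cond_prob_matrix()].
#' @examples
#' cm <- confusion_matrix(diag(10, 3), words = c("a", "b", "c"))
#' row_normalize(cm)
#' @export
row_normalize <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
  rs <- rowSums(cm)
  zero <- which(rs < 1)
  if (length(zero)) {
    stop("no test samples for word(s): ",
         paste(rownames(cm)[zero], collapse = ", "))
  }
  cond_prob_matrix(unclass(cm) / rs, words = rownames(cm))
}

#' Run configuration
#'
#' Bundles the knobs shared across pipeline stages.  All randomness in a
#' run flows from the single integer `seed`, expanded into independent
#' substreams per stage, so that whole runs are bit-reproducible.
#'
#' @param seed integer master seed.
#' @param folds cross-validation folds (at least 2).
#' @param n_boot bootstrap repetitions (at least 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param rho_threshold optional override for the critical Spearman rho;
#'   when `NULL` it is computed exactly from the word-set size.
#' @param tie_decimals optional number of decimals for tie detection when
#'   building orders; `NULL` means exact-value ties.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, folds = 5L, n_boot = 60L, alpha = 0.05,
                       rho_threshold = NULL, tie_decimals = NULL) {
  seed <- as.integer(seed)
  folds <- as.integer(folds)
  n_boot <- as.integer(n_boot)
  stopifnot(folds >= 2L, n_boot >= 1L, alpha > 0, alpha < 1)
  if (!is.null(rho_threshold)) {
    stopifnot(rho_threshold >= -1, rho_threshold <= 1)
  }
  if (!is.null(tie_decimals)) tie_decimals <- as.integer(tie_decimals)
  structure(list(seed = seed, folds = folds, n_boot = n_boot, alpha = alpha,
                 rho_threshold = rho_threshold, tie_decimals = tie_decimals),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path path to a YAML file of flat `key: value` pairs.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}
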