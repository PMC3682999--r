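#' Combine semantic similarity measures
#'
#' Averages a stack of similarity matrices from distinct measures (e.g.
#' path-length, information-content and gloss-vector WordNet measures)
#' into one combined matrix.  With `normalization = "minmax"` each
#' measure is first rescaled to `[0, 1]` over all its entries (diagonal
#' included), so measures on different scales contribute equally.
#'
#' @param measures list of [similarity_matrix()] objects over the same
#'   label set (orders may differ; all are aligned to the first).
#' @param normalization `"none"` or `"minmax"`.
#' @return a [similarity_matrix()].
#' @export
combine_measures <- function(measures, normalization = c("none", "minmax")) {
  normalization <- match.arg(normalization)
  if (!length(measures)) stop("need at least one measure")
  words <- word_labels(measures[[1L]])
  acc <- matrix(0, length(words), length(words))
  for (m in measures) {
    mm <- unclass(align_to_words(m, words))
    if (normalization == "minmax") {
      rng <- range(mm)
      mm <- if (diff(rng) > 0) (mm - rng[1L]) / diff(rng) else mm * 0
    }
    acc <- acc + mm
  }
  similarity_matrix(acc / length(measures), words = as.character(words))
}

#' Read a plain-text corpus
#'
#' One document per line, whitespace-tokenized and lowercased.
#'
#' @param path path to the corpus file.
#' @return a list of character vectors (one per document), class
#'   `"corpus"`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  docs <- lapply(strsplit(tolower(lines), "[[:space:]]+"),
                 function(x) x[nzchar(x)])
  docs <- docs[lengths(docs) > 0L]
  as_corpus(docs)
}

#' @rdname read_corpus
#' @param docs list of token vectors.
#' @export
as_corpus <- function(docs) {
  if (length(docs) < 2L) stop("a corpus needs at least 2 documents")
  structure(lapply(docs, as.character), class = "corpus")
}

#' Word similarity by latent semantic analysis
#'
#' Builds a term-document matrix over the corpus, applies the chosen
#' weighting (log-entropy is the standard choice: local weight
#' `log2(1 + tf)` times a global weight of one minus the normalized
#' entropy of the term's document distribution), truncates its singular
#' value decomposition at `min(max_factors, rank)`, and returns the
#' cosine similarity between the scaled term vectors (term rows of U
#' times the singular values) for the requested words.
#'
#' @param corpus a [read_corpus()] / [as_corpus()] object.
#' @param words the [word_set()] to compare; every word must occur in
#'   the corpus (matching is case-insensitive, as the corpus is
#'   lowercased).
#' @param max_factors maximum number of singular factors retained.
#' @param weighting `"log-entropy"` or raw `"tf"`.
#' @return a [similarity_matrix()] with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
lsa_term_similarity <- function(corpus, words, max_factors = 300L,
                                weighting = c("log-entropy", "tf")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(corpus, "corpus"), max_factors >= 1L)
  words <- as_word_set(words)
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  key <- tolower(as.character(words))
  missing <- as.character(words)[!key %in% vocab]
  if (length(missing)) {
    stop("word(s) absent from the corpus: ",
         paste(missing, collapse = ", "))
  }
  nd <- length(corpus)
  tdm <- matrix(0, length(vocab), nd, dimnames = list(vocab, NULL))
  for (d in seq_len(nd)) {
    tab <- table(corpus[[d]])
    tdm[names(tab), d] <- as.numeric(tab)
  }
  if (weighting == "log-entropy") {
    gf <- rowSums(tdm)
    p <- tdm / gf
    plogp <- ifelse(p > 0, p * log(p), 0)
    gw <- 1 + rowSums(plogp) / log(nd)
    tdm <- log2(1 + tdm) * gw
  }
  sv <- svd(tdm)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(as.integer(max_factors), rank)
  term_vec <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  rownames(term_vec) <- vocab
  tv <- term_vec[key, , drop = FALSE]
  norms <- sqrt(rowSums(tv^2))
  if (any(norms <= .Machine$double.eps)) {
    # a uniformly-distributed term gets zero log-entropy weight
    stop("zero-weight term vector(s) for: ",
         paste(as.character(words)[norms <= .Machine$double.eps],
               collapse = ", "))
  }
  sims <- (tv / norms) %*% t(tv / norms)
  sims <- pmin(pmax(sims, -1), 1)
  diag(sims) <- 1
  dimnames(sims) <- list(as.character(words), as.character(words))
  similarity_matrix(sims)
}
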