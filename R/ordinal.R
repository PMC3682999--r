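#' Strict partial orders of similarity differences
#'
#' For a focus word w, the row of similarity values (or conditional
#' probabilities) against all N words induces an ordinal relation of
#' similarity differences: word j sits above word i exactly when j is
#' strictly more similar to w than i is.  The relation is encoded as a
#' binary connection matrix with `conn[i, j] = 1` iff `value[j] >
#' value[i]`; ties (equal values, optionally after rounding) leave both
#' directions 0 and so become incomparabilities.  The result is
#' irreflexive, asymmetric and transitive by construction, and those
#' invariants are asserted on every constructed order.
#'
#' @param values numeric vector of length N, named by the word labels (or
#'   accompanied by `words`); the focus word's own value is included.
#' @param focus the focus word label (or index into `words`).
#' @param tie_decimals optional integer: round values to this many
#'   decimals before comparing, so that printed-precision ties (e.g. 0.00
#'   vs 0.000) are honoured.  `NULL` compares exact values with a 1e-12
#'   equality tolerance.
#' @param words optional word set when `values` is unnamed.
#' @return an object of class `"strict_partial_order"`: a list with
#'   `words`, `focus`, `conn` (0/1 integer matrix) and `values`.
#' @examples
#' v <- c(a = 3, b = 1, c = 2)
#' build_connection_matrix(v, focus = "a")$conn
#' @export
build_connection_matrix <- function(values, focus, tie_decimals = NULL,
                                    words = NULL) {
  if (is.null(words)) {
    if (is.null(names(values))) stop("values must be named by word labels")
    words <- word_set(names(values))
  } else {
    words <- as_word_set(words)
    if (length(values) != length(words)) {
      stop("values length ", length(values), " does not match word set of ",
           length(words))
    }
    names(values) <- as.character(words)
  }
  if (any(!is.finite(values))) {
    stop("non-finite similarity value(s) for: ",
         paste(names(values)[!is.finite(values)], collapse = ", "))
  }
  if (is.numeric(focus)) focus <- as.character(words)[focus]
  if (!focus %in% as.character(words)) {
    stop("focus word '", focus, "' is not in the word set")
  }
  v <- as.numeric(values)
  if (!is.null(tie_decimals)) v <- round(v, tie_decimals)
  n <- length(v)
  # conn[i, j] = 1 iff j strictly more similar to focus than i
  diff <- outer(v, v, function(a, b) b - a)
  conn <- (diff > 1e-12) * 1L
  storage.mode(conn) <- "integer"
  dimnames(conn) <- list(as.character(words), as.character(words))
  out <- structure(list(words = words, focus = focus, conn = conn,
                        values = stats::setNames(v, as.character(words))),
                   class = "strict_partial_order")
  validate_order(out)
  out
}

#' @rdname build_connection_matrix
#' @param conn a 0/1 square matrix with word dimnames, already encoding a
#'   strict partial order (e.g. a printed connection matrix).
#' @export
strict_partial_order <- function(conn, focus, words = NULL) {
  conn <- check_square_labeled(conn, words, "connection matrix")
  if (!all(conn %in% c(0, 1))) stop("connection matrix must be 0/1")
  storage.mode(conn) <- "integer"
  words <- word_set(rownames(conn))
  if (is.numeric(focus)) focus <- as.character(words)[focus]
  out <- structure(list(words = words, focus = focus, conn = conn,
                        values = NULL),
                   class = "strict_partial_order")
  validate_order(out)
  out
}

validate_order <- function(ord) {
  conn <- ord$conn
  if (any(diag(conn) != 0L)) stop("order is not irreflexive")
  if (any(conn * t(conn) != 0L)) stop("order is not asymmetric")
  comp <- (conn %*% conn) > 0L
  if (any(comp & conn == 0L)) stop("order is not transitive")
  invisible(ord)
}

#' @export
print.strict_partial_order <- function(x, ...) {
  cat("Strict partial order of similarity differences\n")
  cat("  focus:", x$focus, " words:", length(x$words),
      " strict pairs:", sum(x$conn), "\n")
  invisible(x)
}

check_same_order_frame <- function(a, b) {
  stopifnot(inherits(a, "strict_partial_order"),
            inherits(b, "strict_partial_order"))
  if (!identical(as.character(a$words), as.character(b$words))) {
    stop("orders are over different word sets")
  }
  if (!identical(a$focus, b$focus)) {
    stop("orders have different focus words: ", a$focus, " vs ", b$focus)
  }
  invisible(TRUE)
}

#' Build one order per word from a labeled matrix
#'
#' Applies [build_connection_matrix()] to every row of a conditional
#' probability or similarity matrix, giving the family of N per-word
#' orders that jointly represent the structure.
#'
#' @param m a [cond_prob_matrix()] or [similarity_matrix()] (rows are the
#'   focus words).
#' @inheritParams build_connection_matrix
#' @return a list of class `"order_family"` with one
#'   `strict_partial_order` per word, named by the focus words.
#' @export
order_family <- function(m, tie_decimals = NULL) {
  words <- word_labels(m)
  orders <- lapply(as.character(words), function(w) {
    build_connection_matrix(unclass(m)[w, ], focus = w,
                            tie_decimals = tie_decimals)
  })
  names(orders) <- as.character(words)
  structure(list(words = words, orders = orders, source = m),
            class = "order_family")
}

#' Compare or intersect two strict partial orders
#'
#' `orders_identical()` is the label-preserving order-isomorphism check:
#' two orders over the same word set are isomorphic as labeled structures
#' exactly when their connection matrices agree element by element.
#' `intersect_orders()` forms the invariant order, the element-wise AND
#' of the connection matrices, which is again a strict partial order.
#'
#' @param a,b `strict_partial_order` objects over the same word set and
#'   focus.
#' @return `orders_identical()` a logical; `intersect_orders()` a
#'   `strict_partial_order`.
#' @export
orders_identical <- function(a, b) {
  check_same_order_frame(a, b)
  all(a$conn == b$conn)
}

#' @rdname orders_identical
#' @export
intersect_orders <- function(a, b) {
  check_same_order_frame(a, b)
  conn <- a$conn * b$conn
  out <- structure(list(words = a$words, focus = a$focus, conn = conn,
                        values = NULL),
                   class = "strict_partial_order")
  # transitivity of an intersection of transitive relations always holds;
  # asserted anyway as an internal consistency check
  validate_order(out)
  out
}

# Transitive reduction of a DAG given as a 0/1 adjacency matrix.
transitive_reduction <- function(adj) {
  n <- nrow(adj)
  closure <- adj > 0
  for (k in seq_len(n)) {
    closure <- closure | (closure[, k] %o% closure[k, ])
  }
  # drop edge i->j if a longer path i->k->...->j exists
  red <- (adj > 0) & !((adj %*% closure) > 0)
  storage.mode(red) <- "integer"
  dimnames(red) <- dimnames(adj)
  red
}

#' Enumerate the maximal chains of a strict partial order
#'
#' A maximal chain is a totally ordered subset that no word can extend.
#' For an order built from a real-valued row this amounts to sorting the
#' words by value (most similar first) and taking one representative per
#' tie group in every combination, so the number of chains is the product
#' of the tie-group sizes.  The implementation is general: maximal chains
#' are enumerated as source-to-sink paths of the order's transitive
#' reduction (every maximal chain of a finite poset is saturated), so it
#' applies equally to intersected orders.
#'
#' Chains are reported from most similar to least similar (the focus word
#' first when it strictly dominates), in deterministic lexicographic
#' order of word indices.
#'
#' @param order a `strict_partial_order`.
#' @return an object of class `"chain_set"`: list with `focus`, `words`
#'   and `chains` (a list of character vectors).
#' @export
maximal_chains <- function(order) {
  stopifnot(inherits(order, "strict_partial_order"))
  conn <- order$conn
  n <- nrow(conn)
  labels <- rownames(conn)
  # edge i -> j in conn means j is ABOVE i (more similar to the focus);
  # enumerate upward paths, then reverse so chains read top-down.
  red <- transitive_reduction(conn)
  minimal <- which(colSums(conn) == 0L)  # nothing below them
  chains <- list()
  walk <- function(path) {
    i <- path[length(path)]
    ups <- which(red[i, ] > 0L)
    if (!length(ups)) {
      chains[[length(chains) + 1L]] <<- rev(path)
      return(invisible(NULL))
    }
    for (j in ups) walk(c(path, j))
  }
  for (i in minimal) walk(i)
  # antichain nodes are both minimal and maximal and appear once each
  chains <- lapply(chains, function(idx) labels[idx])
  ord <- order(vapply(chains, function(ch) {
    paste(sprintf("%04d", match(ch, labels)), collapse = " ")
  }, character(1)))
  structure(list(focus = order$focus, words = order$words,
                 chains = chains[ord]),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("Chain set for focus '", x$focus, "': ", length(x$chains),
      " maximal chain(s)\n", sep = "")
  for (ch in x$chains) cat("  ", paste(ch, collapse = " > "), "\n")
  invisible(x)
}

# All distinct longest common subsequences of two character vectors.
# Classic dynamic program over prefix lengths with a memoized backtrack;
# sequences are deduplicated via a control-character join.
all_lcs <- function(a, b) {
  na <- length(a); nb <- length(b)
  L <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      L[i + 1L, j + 1L] <- if (a[i] == b[j]) {
        L[i, j] + 1L
      } else {
        max(L[i, j + 1L], L[i + 1L, j])
      }
    }
  }
  memo <- new.env(parent = emptyenv())
  back <- function(i, j) {
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0L || j == 0L) {
      ""
    } else if (a[i] == b[j]) {
      pre <- back(i - 1L, j - 1L)
      paste0(pre, ifelse(nzchar(pre), "\x1f", ""), a[i])
    } else {
      out <- character(0)
      if (L[i, j + 1L] == L[i + 1L, j + 1L]) out <- c(out, back(i - 1L, j))
      if (L[i + 1L, j] == L[i + 1L, j + 1L]) out <- c(out, back(i, j - 1L))
      unique(out)
    }
    memo[[key]] <- res
    res
  }
  list(length = L[na + 1L, nb + 1L],
       seqs = unique(strsplit(back(na, nb), "\x1f", fixed = TRUE)))
}

#' Invariant orders as maximal-length common subsequences
#'
#' Given the maximal chains of a brain-derived order and of a
#' semantic-model-derived order for the same focus word, the invariant
#' partial orders are the common subsequences of maximal length over all
#' pairs of chains: shared orderings present in both structures.  The
#' element-wise intersection of the two connection matrices is returned
#' alongside; every invariant chain is a chain of that intersected order.
#'
#' @param a,b `chain_set` objects for the same focus and word set (see
#'   [maximal_chains()]).  Alternatively `strict_partial_order` objects,
#'   whose chains are computed first.
#' @return an object of class `"invariant_result"`: list with `focus`,
#'   `invariant_chains` (deduplicated, lexicographically ordered list of
#'   word-label vectors), `max_length`, and `intersected_order` when the
#'   input orders are available.
#' @export
maximal_common_subsequences <- function(a, b) {
  inter <- NULL
  if (inherits(a, "strict_partial_order")) {
    inter <- intersect_orders(a, b)
    a <- maximal_chains(a); b <- maximal_chains(b)
  }
  stopifnot(inherits(a, "chain_set"), inherits(b, "chain_set"))
  if (!identical(a$focus, b$focus)) {
    stop("chain sets have different focus words")
  }
  if (!identical(as.character(a$words), as.character(b$words))) {
    stop("chain sets are over different word sets")
  }
  if (!length(a$chains) || !length(b$chains)) stop("empty chain set")
  best_len <- 0L
  pool <- character(0)
  for (ca in a$chains) {
    for (cb in b$chains) {
      r <- all_lcs(ca, cb)
      if (r$length > best_len) {
        best_len <- r$length
        pool <- character(0)
      }
      if (r$length == best_len && best_len > 0L) {
        pool <- c(pool, vapply(r$seqs, paste, character(1),
                               collapse = "\x1f"))
      }
    }
  }
  chains <- lapply(unique(pool), function(s) {
    strsplit(s, "\x1f", fixed = TRUE)[[1L]]
  })
  labels <- as.character(a$words)
  ord <- order(vapply(chains, function(ch) {
    paste(sprintf("%04d", match(ch, labels)), collapse = " ")
  }, character(1)))
  structure(list(focus = a$focus, words = a$words,
                 invariant_chains = chains[ord],
                 max_length = best_len,
                 intersected_order = inter),
            class = "invariant_result")
}

#' @export
print.invariant_result <- function(x, ...) {
  cat("Invariant orders for focus '", x$focus, "': ",
      length(x$invariant_chains), " chain(s) of length ", x$max_length,
      "\n", sep = "")
  for (ch in x$invariant_chains) cat("  ", paste(ch, collapse = " > "), "\n")
  invisible(x)
}

#' Join invariant chains into one DAG
#'
#' Takes the union of consecutive-pair edges over all invariant chains,
#' transitively reduces it, and returns the edge list of the resulting
#' directed acyclic graph (arrows point from more similar to less
#' similar, as in the printed joint-order figures).
#'
#' @param inv an `invariant_result` with at least one invariant chain.
#' @return a data frame with columns `from` and `to`.
#' @export
join_invariants <- function(inv) {
  stopifnot(inherits(inv, "invariant_result"))
  if (!length(inv$invariant_chains)) stop("no invariant chains to join")
  labels <- as.character(inv$words)
  n <- length(labels)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (ch in inv$invariant_chains) {
    if (length(ch) < 2L) next
    idx <- match(ch, labels)
    for (k in seq_len(length(idx) - 1L)) {
      adj[idx[k], idx[k + 1L]] <- 1L
    }
  }
  # acyclicity check: transitive closure must stay irreflexive
  closure <- adj > 0
  for (k in seq_len(n)) closure <- closure | (closure[, k] %o% closure[k, ])
  if (any(diag(closure))) stop("internal error: joined invariants are cyclic")
  red <- transitive_reduction(adj)
  e <- which(red > 0L, arr.ind = TRUE)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  data.frame(from = labels[e[, 1L]], to = labels[e[, 2L]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a joined invariant DAG in DOT format
#'
#' @param edges edge data frame from [join_invariants()].
#' @param path output file path.
#' @param name graph name.
#' @return `path`, invisibly.
#' @export
write_dot <- function(edges, path, name = "invariant") {
  lines <- c(sprintf("digraph %s {", name),
             sprintf("  \"%s\" -> \"%s\";", edges$from, edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
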