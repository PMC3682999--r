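fx <- geography_fixtures()

test_that("connection matrices follow the printed orientation", {
  # published language column reproduces the published connection matrix
  ord <- build_connection_matrix(fx$table1$language, "London")
  expect_equal(ord$conn, fx$connection_language_london,
               ignore_attr = FALSE)
  # tiny forced example: values (3, 1, 2) for (a, b, c)
  ord2 <- build_connection_matrix(c(a = 3, b = 1, c = 2), "a")
  expect_equal(unname(ord2$conn),
               matrix(c(0L, 0L, 0L,
                        1L, 0L, 1L,
                        1L, 0L, 0L), 3, byrow = TRUE))
  # total tie gives the empty order
  ord3 <- build_connection_matrix(c(a = 1, b = 1, c = 1), "a")
  expect_true(all(ord3$conn == 0L))
  expect_error(build_connection_matrix(c(a = 1, b = NaN), "a"),
               "non-finite")
})

test_that("orders from value rows are strict partial orders with the tie-count law", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    vals <- random_value_row(k)
    ord <- build_connection_matrix(vals, names(vals)[1])
    conn <- ord$conn
    expect_true(all(diag(conn) == 0L))                    # irreflexive
    expect_true(all(conn * t(conn) == 0L))                # asymmetric
    expect_true(all(((conn %*% conn) > 0) <= (conn > 0))) # transitive
    groups <- table(vals)
    expect_equal(sum(conn),
                 choose(k, 2) - sum(choose(groups, 2)))
  }
})

test_that("tie rounding controls which values compare equal", {
  vals <- c(a = 0.123, b = 0.1234, c = 0.5)
  sharp <- build_connection_matrix(vals, "a")
  expect_equal(sum(sharp$conn), 3L)     # all three distinct
  blunt <- build_connection_matrix(vals, "a", tie_decimals = 3)
  expect_equal(sum(blunt$conn), 2L)     # a and b tie at 3 decimals
})

test_that("orders_identical is element-wise label-preserving isomorphism", {
  lang <- build_connection_matrix(fx$table1$language, "London")
  expect_true(orders_identical(lang, lang))
  # the brain-derived order differs from the language-derived order
  brain <- build_connection_matrix(fx$table1$brain, "London")
  expect_false(orders_identical(lang, brain))
  # the two published connection matrices differ in their highlighted cells
  t2 <- strict_partial_order(fx$connection_brain_london, "London")
  t3 <- strict_partial_order(fx$connection_language_london, "London")
  expect_false(orders_identical(t2, t3))
  # flipping one asymmetric edge breaks identity
  conn <- lang$conn
  edge <- which(conn == 1L, arr.ind = TRUE)[1L, ]
  conn[edge[1L], edge[2L]] <- 0L
  conn[edge[2L], edge[1L]] <- 1L
  flipped <- tryCatch(strict_partial_order(conn, "London"),
                      error = function(e) NULL)
  if (!is.null(flipped)) expect_false(orders_identical(lang, flipped))
  expect_error(orders_identical(lang,
    build_connection_matrix(c(x = 1, y = 2), "x")), "word sets")
})

test_that("intersect_orders matches a brute-force pair scan", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    va <- random_value_row(k); vb <- random_value_row(k)
    a <- build_connection_matrix(va, "w1")
    b <- build_connection_matrix(vb, "w1")
    inter <- intersect_orders(a, b)
    for (p in seq_len(k)) {
      for (q in seq_len(k)) {
        expect_identical(inter$conn[p, q],
                         a$conn[p, q] * b$conn[p, q])
      }
    }
    expect_true(orders_identical(intersect_orders(a, a), a))
    empty <- build_connection_matrix(rep(1, k) |>
      stats::setNames(names(va)), "w1")
    expect_true(all(intersect_orders(a, empty)$conn == 0L))
  }
})

test_that("maximal chains agree with the tie-group construction", {
  set.seed(13)
  chain_key <- function(chs) sort(vapply(chs, paste, character(1),
                                         collapse = " "))
  for (i in 1:20) {
    k <- sample(3:7, 1)
    vals <- random_value_row(k, tie_prob = 0.6)
    ord <- build_connection_matrix(vals, names(vals)[1])
    got <- maximal_chains(ord)$chains
    want <- chains_from_values(vals)
    expect_equal(chain_key(got), chain_key(want))
    # chain-count and chain-length laws
    groups <- as.integer(table(vals))
    expect_length(got, prod(groups))
    expect_true(all(lengths(got) == k - sum(groups - 1L)))
  }
  # a full antichain decomposes into singleton chains
  anti <- build_connection_matrix(c(a = 2, b = 2, c = 2), "a")
  expect_equal(maximal_chains(anti)$chains, list("a", "b", "c"))
})

test_that("published worked-example chains come out exactly", {
  lang_ch <- maximal_chains(
    build_connection_matrix(fx$table1$language, "London"))
  expect_length(lang_ch$chains, 1L)
  expect_equal(lang_ch$chains[[1L]],
               c("London", "Paris", "Moscow", "Germany", "Russia",
                 "Poland", "north", "south", "west", "east"))
  brain_ch <- maximal_chains(
    build_connection_matrix(fx$table1$brain, "London"))
  expect_length(brain_ch$chains, 2L)
  expect_true(all(lengths(brain_ch$chains) == 9L))
  expect_equal(sort(vapply(brain_ch$chains, tail, "", n = 1)),
               c("south", "west"))
})

test_that("maximal common subsequences match brute force on small orders", {
  set.seed(17)
  key <- function(chs) sort(vapply(chs, paste, character(1),
                                   collapse = " "))
  for (i in 1:12) {
    k <- sample(4:6, 1)
    va <- random_value_row(k, tie_prob = 0.6)
    vb <- random_value_row(k, tie_prob = 0.6)
    a <- build_connection_matrix(va, "w1")
    b <- build_connection_matrix(vb, "w1")
    inv <- maximal_common_subsequences(a, b)
    want <- brute_mcs(maximal_chains(a)$chains, maximal_chains(b)$chains)
    expect_equal(key(inv$invariant_chains), key(want))
    expect_equal(inv$max_length, max(lengths(want)))
    # every invariant chain is a subsequence of a chain in each family
    is_subseq <- function(s, ch) {
      pos <- match(s, ch)
      !anyNA(pos) && !is.unsorted(pos, strictly = TRUE)
    }
    for (s in inv$invariant_chains) {
      expect_true(any(vapply(maximal_chains(a)$chains, is_subseq,
                             TRUE, s = s)))
      expect_true(any(vapply(maximal_chains(b)$chains, is_subseq,
                             TRUE, s = s)))
    }
    expect_lte(inv$max_length,
               min(lengths(maximal_chains(a)$chains),
                   lengths(maximal_chains(b)$chains)))
  }
})

test_that("degenerate common-subsequence cases behave", {
  ws <- word_set(c("a", "b", "c"))
  up <- build_connection_matrix(c(a = 3, b = 2, c = 1), "a")
  down <- build_connection_matrix(c(a = 1, b = 2, c = 3), "a")
  same <- maximal_common_subsequences(up, up)
  expect_equal(same$invariant_chains, list(c("a", "b", "c")))
  expect_equal(same$max_length, 3L)
  rev <- maximal_common_subsequences(up, down)
  expect_equal(rev$max_length, 1L)
  expect_equal(sort(unlist(rev$invariant_chains)), c("a", "b", "c"))
})

test_that("joined invariants form the expected reduced DAG", {
  lang <- build_connection_matrix(fx$table1$language, "London")
  brain <- build_connection_matrix(fx$table1$brain, "London")
  inv <- maximal_common_subsequences(brain, lang)
  edges <- join_invariants(inv)
  # shared six-node path then a branch into south, west and east
  spine <- c("London", "Paris", "Moscow", "Germany", "Russia", "Poland")
  for (k in 1:5) {
    expect_true(any(edges$from == spine[k] & edges$to == spine[k + 1]))
  }
  expect_equal(sort(edges$to[edges$from == "Poland"]),
               c("east", "south", "west"))
  expect_equal(nrow(edges), 8L)
  # single chain reduces to its own path
  single <- maximal_common_subsequences(lang, lang)
  e1 <- join_invariants(single)
  expect_equal(nrow(e1), 9L)
})
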