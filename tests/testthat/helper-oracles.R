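# Shared helpers and independent oracles for the test suite.

# Scaled-down generator configuration used by end-to-end tests: 6
# channels, 20-sample epochs (offset 4, extension 10), 30 trials per
# word, snr 1.6 (the ~25% single-trial accuracy regime at this scale).
scaled_generator <- function(seed, snr = 1.6, trials = 30L) {
  generator_spec(trials_per_word = trials, channels = 6L, epoch_len = 20L,
                 snr = snr, seed = seed, offset_samples = 4L,
                 extension_samples = 10L)
}

scaled_epochs <- function(sim) extract_epochs(sim$recording, 4L, 10L)

# All permutations of 1..n as a matrix (rows), recursively.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# Brute-force exact critical rho: enumerate every rank permutation.
brute_critical_rho <- function(n, alpha) {
  perms <- all_permutations(n)
  d2 <- rowSums((perms - rep(seq_len(n), each = nrow(perms)))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  tab <- sort(unique(rho), decreasing = TRUE)
  tail_p <- vapply(tab, function(r) mean(rho >= r - 1e-12), numeric(1))
  ok <- tab[tail_p <= alpha / 2 + 1e-12]
  if (!length(ok)) NA_real_ else min(ok)
}

# Independent construction of maximal chains for an order built from a
# value row: sort descending, form tie groups, take every combination
# of one representative per group.
chains_from_values <- function(values) {
  v <- sort(unique(values), decreasing = TRUE)
  groups <- lapply(v, function(val) names(values)[values == val])
  combos <- expand.grid(groups, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) unname(unlist(combos[i, ])))
}

# All subsequences of a character vector (including the empty one).
all_subsequences <- function(x) {
  n <- length(x)
  idx <- 0:(2^n - 1)
  lapply(idx, function(m) x[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
}

# Brute-force maximal common subsequences between two chain sets.
brute_mcs <- function(chains_a, chains_b) {
  key <- function(s) paste(s, collapse = "\x1f")
  sub_a <- unique(unlist(lapply(chains_a, function(ch) {
    vapply(all_subsequences(ch), key, character(1))
  })))
  sub_b <- unique(unlist(lapply(chains_b, function(ch) {
    vapply(all_subsequences(ch), key, character(1))
  })))
  common <- intersect(sub_a, sub_b)
  seqs <- strsplit(common, "\x1f", fixed = TRUE)
  lens <- lengths(seqs)
  seqs[lens == max(lens) & max(lens) > 0]
}

# Naive complete-linkage agglomeration on a distance matrix; returns
# the sorted vector of merge heights.
naive_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Random named value row over k words, with optional forced ties.
random_value_row <- function(k, tie_prob = 0.3) {
  vals <- round(runif(k), 2)
  if (tie_prob > 0 && k >= 3 && runif(1) < tie_prob) {
    vals[2] <- vals[1]
  }
  names(vals) <- paste0("w", seq_len(k))
  vals
}
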