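make_recording <- function(durations, channels = 15L, gap = 5L,
                           total_pad = 200L) {
  n <- length(durations)
  onsets <- cumsum(c(0L, utils::head(durations + gap + 60L, -1L)))
  time_len <- max(onsets + durations) + total_pad
  sig <- matrix(seq_len(channels * time_len) / 1000, channels, time_len)
  ev <- data.frame(trial = seq_len(n),
                   word = rep(c("alpha", "beta"), length.out = n),
                   onset_sample = onsets,
                   offset_sample = onsets + durations)
  recording(sig, 62.5, ev)
}

test_that("epoch length follows the floored mean extended duration", {
  rec1 <- make_recording(c(20L, 20L))
  ds1 <- extract_epochs(rec1, offset_samples = 10L,
                        extension_samples = 50L)
  expect_equal(ds1$epoch_len, 70L)
  expect_equal(ncol(ds1$features), 15L * 70L)
  rec2 <- make_recording(c(10L, 20L))
  ds2 <- extract_epochs(rec2, 10L, 50L)
  expect_equal(ds2$epoch_len, floor((60 + 70) / 2))
  # the default 10-sample start shift is 160 ms at 62.5 Hz
  expect_equal(10 / rec1$rate_hz * 1000, 160)
})

test_that("epoch windows index the right samples per channel", {
  rec <- make_recording(c(12L, 12L), channels = 3L)
  ds <- extract_epochs(rec, offset_samples = 2L, extension_samples = 4L)
  L <- ds$epoch_len
  expect_equal(L, 16L)
  on <- rec$events$onset_sample[1L]
  want <- as.vector(t(rec$signal[, (on + 2 + 1):(on + 2 + L)]))
  expect_equal(ds$features[1L, ], want)
})

test_that("epochs never run past the signal; no silent padding", {
  rec <- make_recording(c(20L, 20L), total_pad = 10L)
  expect_error(extract_epochs(rec, 10L, 50L), "past the end")
  expect_error(extract_epochs(
    recording(matrix(0, 2, 100), 62.5,
              data.frame(trial = integer(), word = character(),
                         onset_sample = integer(),
                         offset_sample = integer())), 1L, 1L),
    "no events")
})

separable_dataset <- function(n_per = 10L, dim = 24L, words = 3L) {
  labs <- paste0("w", seq_len(words))
  feats <- matrix(0, n_per * words, dim)
  labels <- rep(labs, each = n_per)
  for (k in seq_len(words)) {
    proto <- rep(0, dim); proto[k] <- 50
    rows <- which(labels == labs[k])
    feats[rows, ] <- matrix(proto, n_per, dim, byrow = TRUE) +
      matrix(rnorm(n_per * dim, sd = 0.01), n_per, dim)
  }
  structure(list(words = word_set(labs), features = feats,
                 labels = labels, epoch_len = dim, channels = 1L,
                 rate_hz = 62.5),
            class = "trial_dataset")
}

test_that("classifier is perfect on separable prototypes and counts sum to T", {
  set.seed(2)
  ds <- separable_dataset()
  cm <- classify_cv(ds, classifier_spec(pca_variance = 1, shrinkage = 0),
                    seed = 4)
  expect_equal(sum(cm), length(ds$labels))
  expect_equal(sum(diag(cm)), length(ds$labels))   # accuracy 1.0
})

test_that("fold assignment and confusion counts are seed-deterministic", {
  set.seed(99)
  sim <- simulate_trials(scaled_generator(3, trials = 10L))
  ds <- scaled_epochs(sim)
  a <- classify_cv(ds, classifier_spec(), seed = 12)
  b <- classify_cv(ds, classifier_spec(), seed = 12)
  c3 <- classify_cv(ds, classifier_spec(), seed = 13)
  expect_identical(a, b)
  expect_false(identical(a, c3))
  expect_error(classify_cv(ds, classifier_spec(folds = 11L), seed = 1),
               "fewer samples than folds")
})

test_that("label-shuffled data classify at chance", {
  set.seed(31)
  sim <- simulate_trials(scaled_generator(8, trials = 20L))
  ds <- scaled_epochs(sim)
  ds$labels <- sample(ds$labels)      # break the label-signal link
  cm <- classify_cv(ds, classifier_spec(), seed = 5)
  t_tot <- sum(cm)
  acc_count <- sum(diag(cm))
  n_words <- length(ds$words)
  band <- qbinom(c(0.005, 0.995), t_tot, 1 / n_words)
  expect_gte(acc_count, band[1L])
  expect_lte(acc_count, band[2L])
})

test_that("accuracy is non-decreasing over a coarse SNR grid", {
  accs <- vapply(c(0.4, 1.6, 6), function(snr) {
    acc <- 0
    for (s in 1:2) {
      sim <- simulate_trials(scaled_generator(100 + s, snr = snr,
                                              trials = 15L))
      ds <- scaled_epochs(sim)
      cm <- classify_cv(ds, classifier_spec(), seed = s)
      acc <- acc + sum(diag(cm)) / sum(cm) / 2
    }
    acc
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("shrinkage-free classifier agrees with a reference discriminant", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 40L; p <- 6L
  labs <- rep(c("a", "b", "c", "d"), each = n / 4)
  x <- matrix(rnorm(n * p), n, p) +
    outer(as.integer(factor(labs)), seq_len(p), function(a, b) a * b / 2)
  xte <- matrix(rnorm(20L * p), 20L, p)
  fit <- MASS::lda(x, grouping = labs)
  want <- as.character(predict(fit, xte)$class)
  got <- ordsim:::fit_predict_lda(x, labs, xte, pca_variance = 1,
                                  shrinkage = 0)
  expect_equal(got, want)
})

test_that("a single non-resampled repetition reproduces classify_cv", {
  set.seed(41)
  sim <- simulate_trials(scaled_generator(6, trials = 10L))
  ds <- scaled_epochs(sim)
  boot <- bootstrap_classify(ds, classifier_spec(), n_boot = 1L,
                             seed = 77, resample = FALSE)
  expect_identical(boot[[1L]], classify_cv(ds, classifier_spec(),
                                           seed = 77))
})

test_that("bootstrap preserves class counts and is reproducible", {
  sim <- simulate_trials(scaled_generator(9, trials = 8L))
  ds <- scaled_epochs(sim)
  boots <- bootstrap_classify(ds, classifier_spec(), n_boot = 3L,
                              seed = 5)
  for (cm in boots) {
    expect_equal(unname(rowSums(cm)[as.character(ds$words)]),
                 as.numeric(table(ds$labels)[as.character(ds$words)]))
  }
  again <- bootstrap_classify(ds, classifier_spec(), n_boot = 3L,
                              seed = 5)
  expect_identical(boots, again)
})

test_that("bootstrap cell means converge to the no-resampling estimate", {
  # Monte-Carlo check on a small multinomial world: the mean of
  # row-normalized bootstrap matrices approaches the plain estimate
  set.seed(14)
  words <- c("a", "b", "c")
  p <- cond_prob_matrix(matrix(c(0.6, 0.3, 0.1,
                                 0.2, 0.5, 0.3,
                                 0.1, 0.2, 0.7), 3, byrow = TRUE,
                               dimnames = list(words, words)))
  base_cm <- simulate_confusion(p, 60L, seed = 2)
  base_p <- row_normalize(base_cm)
  n_boot <- 200L
  acc <- matrix(0, 3, 3)
  for (b in seq_len(n_boot)) {
    # resample trials within each true class from the observed counts
    res <- t(vapply(seq_len(3), function(i) {
      as.integer(rmultinom(1L, sum(base_cm[i, ]),
                           unclass(base_p)[i, ]))
    }, integer(3)))
    dimnames(res) <- dimnames(base_cm)
    acc <- acc + unclass(row_normalize(confusion_matrix(res)))
  }
  boot_mean <- acc / n_boot
  se <- sqrt(unclass(base_p) * (1 - unclass(base_p)) /
               rowSums(base_cm)) / sqrt(n_boot)
  expect_true(all(abs(boot_mean - unclass(base_p)) <= 3 * se + 1e-9))
})

test_that("cumulative conditional probabilities are running means", {
  words <- c("a", "b", "c")
  p <- cond_prob_matrix(diag(3), words = words)
  cms <- lapply(1:4, function(s) simulate_confusion(
    cond_prob_matrix(matrix(1 / 3, 3, 3, dimnames = list(words, words))),
    30L, seed = s))
  cum <- cumulative_condprob(cms)
  expect_length(cum, 4L)
  expect_equal(unclass(cum[[1L]]), unclass(row_normalize(cms[[1L]])))
  manual <- Reduce(`+`, lapply(cms, function(x)
    unclass(row_normalize(x)))) / 4
  expect_equal(unclass(cum[[4L]]), manual, tolerance = 1e-12)
  expect_true(all(abs(rowSums(cum[[4L]]) - 1) < 1e-9))
  # identical inputs give a constant sequence
  same <- cumulative_condprob(list(cms[[1L]], cms[[1L]]))
  expect_equal(unclass(same[[2L]]), unclass(same[[1L]]))
})

test_that("recordings survive a disk round trip", {
  sim <- simulate_trials(scaled_generator(2, trials = 4L))
  dir <- withr::local_tempdir()
  write_recording(sim$recording, dir)
  back <- read_recording(file.path(dir, "signal.txt"),
                         file.path(dir, "events.tsv"))
  expect_equal(back$events$word, sim$recording$events$word)
  expect_equal(back$signal, sim$recording$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
  ds1 <- scaled_epochs(sim)
  ds2 <- extract_epochs(back, 4L, 10L)
  expect_equal(ds2$features, ds1$features, tolerance = 1e-10)
})
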