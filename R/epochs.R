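#' Multichannel trial recordings
#'
#' A recording is a channels-by-time numeric signal matrix plus a table
#' of word events.  Event onsets and offsets are 0-based sample offsets
#' into the signal (`0 <= onset < offset <= ncol(signal)`), matching the
#' half-open convention of the on-disk events file.
#'
#' @param signal numeric matrix, one row per channel.
#' @param rate_hz effective sampling rate in Hz (62.5 for 1 kHz data
#'   down-sampled 16 times).
#' @param events data frame with columns `trial`, `word`,
#'   `onset_sample`, `offset_sample`.
#' @return an object of class `"recording"`.
#' @export
recording <- function(signal, rate_hz, events) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) < 1L) stop("need at least one channel")
  need <- c("trial", "word", "onset_sample", "offset_sample")
  if (!all(need %in% names(events))) {
    stop("events must have columns: ", paste(need, collapse = ", "))
  }
  events <- as.data.frame(events)[need]
  if (any(events$onset_sample < 0) ||
      any(events$offset_sample <= events$onset_sample) ||
      any(events$offset_sample > ncol(signal))) {
    stop("event onsets/offsets outside the signal bounds")
  }
  structure(list(signal = signal, rate_hz = as.numeric(rate_hz),
                 events = events),
            class = "recording")
}

#' Read a recording from delimited text files
#'
#' The signal file holds the channels-by-time matrix as whitespace- or
#' comma-delimited numbers, one row per channel; the events file is a
#' TSV with columns `trial`, `word`, `onset_sample`, `offset_sample`.
#'
#' @param signal_path path to the signal matrix file.
#' @param events_path path to the events TSV.
#' @param rate_hz sampling rate in Hz.
#' @return a [recording()].
#' @export
read_recording <- function(signal_path, events_path, rate_hz = 62.5) {
  sig <- as.matrix(utils::read.table(signal_path, header = FALSE,
                                     sep = "", comment.char = ""))
  ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
  recording(sig, rate_hz, ev)
}

#' @rdname read_recording
#' @param rec a [recording()].
#' @param dir output directory (created if needed).
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(format(rec$signal, digits = 15, trim = TRUE),
                     file.path(dir, "signal.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(rec$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Extract equal-length word epochs from a recording
#'
#' Each word's sample begins `offset_samples` data points after the
#' word's onset (10 points = 160 ms at 62.5 Hz, past the early acoustic
#' response), and every event is notionally extended by
#' `extension_samples` points (50 points = 800 ms, covering the
#' semantic-integration window); the common epoch length is the floor of
#' the mean extended duration over all events.  Each epoch spans that
#' common length on every channel, and channels are concatenated in
#' channel order into one feature vector per trial.
#'
#' Epochs that would run past the end of the signal are an error, never
#' silently padded, because padding changes feature statistics.
#'
#' @param rec a [recording()].
#' @param offset_samples start-point shift in samples.
#' @param extension_samples duration extension in samples.
#' @return an object of class `"trial_dataset"`: list with `words` (the
#'   word set, in order of first appearance sorted alphabetically),
#'   `features` (trials-by-length matrix), `labels` (character vector),
#'   `epoch_len`, `channels`, `rate_hz`.
#' @export
extract_epochs <- function(rec, offset_samples = 10L,
                           extension_samples = 50L) {
  stopifnot(inherits(rec, "recording"))
  ev <- rec$events
  if (!nrow(ev)) stop("recording has no events")
  dur <- ev$offset_sample - ev$onset_sample
  L <- floor(mean(dur + extension_samples))
  if (L <= 0) stop("computed epoch length is not positive")
  starts <- ev$onset_sample + offset_samples        # 0-based
  ends <- starts + L                                # half-open
  over <- which(ends > ncol(rec$signal))
  if (length(over)) {
    stop("epoch(s) extend past the end of the signal for event(s): ",
         paste(utils::head(over, 10L), collapse = ", "))
  }
  nch <- nrow(rec$signal)
  feats <- matrix(0, nrow(ev), nch * L)
  for (t in seq_len(nrow(ev))) {
    seg <- rec$signal[, (starts[t] + 1L):(starts[t] + L), drop = FALSE]
    feats[t, ] <- as.vector(t(seg))  # channel blocks in channel order
  }
  labels <- as.character(ev$word)
  words <- word_set(sort(unique(labels)))
  structure(list(words = words, features = feats, labels = labels,
                 epoch_len = L, channels = nch, rate_hz = rec$rate_hz),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Trial dataset:", nrow(x$features), "trials,",
      length(x$words), "words,", ncol(x$features),
      "features (", x$channels, "channels x", x$epoch_len, "samples )\n")
  invisible(x)
}

#' Classifier specification
#'
#' The classifier follows the structure of single-trial decoding work:
#' a linear discriminant with a nested principal-component reduction,
#' run in a stratified k-fold cross-validation loop.  Within each
#' training fold the features are centred, rotated onto the smallest
#' number of principal components whose cumulative variance reaches
#' `pca_variance`, and a linear discriminant with a shrinkage-
#' regularized pooled covariance is fitted; the held-out fold is then
#' classified.
#'
#' @param folds number of cross-validation folds (at least 2).
#' @param pca_variance fraction of training variance to retain in (0, 1].
#' @param shrinkage covariance shrinkage toward a scaled identity in
#'   `[0, 1]`, or `NULL` for an automatic Ledoit-Wolf-style estimate.
#' @return list of class `"classifier_spec"`.
#' @export
classifier_spec <- function(folds = 5L, pca_variance = 0.95,
                            shrinkage = NULL) {
  folds <- as.integer(folds)
  stopifnot(folds >= 2L, pca_variance > 0, pca_variance <= 1)
  if (!is.null(shrinkage)) stopifnot(shrinkage >= 0, shrinkage <= 1)
  structure(list(folds = folds, pca_variance = pca_variance,
                 shrinkage = shrinkage),
            class = "classifier_spec")
}

# Stratified fold assignment: within each class, indices are shuffled
# and dealt round-robin, so every class appears in every fold.
stratified_folds <- function(labels, folds, seed) {
  counts <- table(labels)
  short <- names(counts)[counts < folds]
  if (length(short)) {
    stop("class(es) with fewer samples than folds: ",
         paste(short, collapse = ", "))
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (w in names(counts)) {
      idx <- which(labels == w)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# Ledoit-Wolf-style shrinkage intensity for pooled within-class
# covariance, from the centred residuals z (rows) and their covariance S.
lw_shrinkage <- function(z, S) {
  n <- nrow(z)
  p <- ncol(z)
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 <= .Machine$double.eps) return(0)
  zs <- rowSums(z^2)
  b2 <- (sum(zs^2) - 2 * sum(z * (z %*% S)) + n * sum(S^2)) / n^2
  max(0, min(1, b2 / d2))
}

# Fit centred-PCA + shrinkage LDA on training data, classify test rows.
fit_predict_lda <- function(xtr, ytr, xte, pca_variance, shrinkage) {
  centre <- colMeans(xtr)
  xtr <- sweep(xtr, 2L, centre)
  xte <- sweep(xte, 2L, centre)
  sv <- svd(xtr, nu = 0)
  var_exp <- sv$d^2
  keep <- sv$d > max(sv$d) * 1e-10
  var_exp <- var_exp[keep]
  rot <- sv$v[, keep, drop = FALSE]
  ncomp <- which(cumsum(var_exp) / sum(var_exp) >= pca_variance - 1e-12)[1L]
  rot <- rot[, seq_len(ncomp), drop = FALSE]
  ztr <- xtr %*% rot
  zte <- xte %*% rot
  classes <- sort(unique(ytr))
  k <- length(classes)
  p <- ncol(ztr)
  means <- matrix(0, k, p)
  resid <- ztr
  for (ci in seq_len(k)) {
    rows <- ytr == classes[ci]
    means[ci, ] <- colMeans(ztr[rows, , drop = FALSE])
    resid[rows, ] <- sweep(ztr[rows, , drop = FALSE], 2L, means[ci, ])
  }
  S <- crossprod(resid) / (nrow(ztr) - k)
  lam <- if (is.null(shrinkage)) lw_shrinkage(resid, S) else shrinkage
  Sreg <- (1 - lam) * S + lam * diag(mean(diag(S)), p)
  # guard against numerically singular pooled covariance at shrinkage 0
  Sinv <- tryCatch(solve(Sreg),
                   error = function(e) solve(Sreg + diag(1e-8, p)))
  priors <- as.numeric(table(factor(ytr, levels = classes))) / length(ytr)
  W <- Sinv %*% t(means)                       # p x k
  const <- -0.5 * colSums(t(means) * W) + log(priors)
  scores <- zte %*% W + rep(const, each = nrow(zte))
  classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated linear-discriminant classification
#'
#' Runs the classifier of [classifier_spec()] in a stratified k-fold
#' loop: fold assignment is a deterministic function of `(seed,
#' labels)`; the principal-component rotation and discriminant are
#' re-fitted inside every training fold (nested, so no test information
#' leaks); predictions for all held-out folds are accumulated into a
#' confusion matrix whose counts sum to the number of trials.
#'
#' @param ds a `trial_dataset` from [extract_epochs()] or
#'   [simulate_trials()].
#' @param spec a [classifier_spec()].
#' @param seed integer seed for the fold assignment.
#' @return a [confusion_matrix()] (rows = true word, columns = predicted
#'   word).
#' @export
classify_cv <- function(ds, spec = classifier_spec(), seed = 1L) {
  stopifnot(inherits(ds, "trial_dataset"))
  labels <- ds$labels
  words <- as.character(ds$words)
  fold <- stratified_folds(labels, spec$folds, seed)
  pred <- character(length(labels))
  for (f in seq_len(spec$folds)) {
    te <- fold == f
    pred[te] <- fit_predict_lda(ds$features[!te, , drop = FALSE],
                                labels[!te],
                                ds$features[te, , drop = FALSE],
                                spec$pca_variance, spec$shrinkage)
  }
  counts <- table(factor(labels, levels = words),
                  factor(pred, levels = words))
  confusion_matrix(matrix(as.integer(counts), length(words),
                          dimnames = list(words, words)))
}

#' Bootstrap repetition of single-trial classification
#'
#' Repeats [classify_cv()] `n_boot` times; in each repetition the trials
#' are resampled with replacement within each word class (class counts
#' preserved, so every word stays estimable in every repetition), and
#' the classifier is re-run with a fresh fold seed derived from `seed`.
#'
#' @inheritParams classify_cv
#' @param n_boot number of repetitions.
#' @param resample set `FALSE` to disable resampling, in which case each
#'   repetition only re-randomizes the fold assignment (and `n_boot = 1`
#'   reproduces [classify_cv()] exactly).
#' @return a list of [confusion_matrix()] objects, one per repetition.
#' @export
bootstrap_classify <- function(ds, spec = classifier_spec(), n_boot = 60L,
                               seed = 1L, resample = TRUE) {
  stopifnot(inherits(ds, "trial_dataset"), n_boot >= 1L)
  out <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    ds_b <- ds
    if (resample) {
      idx <- with_seed(stage_seed(seed, "boot-resample", b), {
        unlist(lapply(as.character(ds$words), function(w) {
          rows <- which(ds$labels == w)
          rows[sample.int(length(rows), length(rows), replace = TRUE)]
        }), use.names = FALSE)
      })
      ds_b$features <- ds$features[idx, , drop = FALSE]
      ds_b$labels <- ds$labels[idx]
    }
    # repetition 1 reuses the master seed so that a single non-resampled
    # repetition reproduces classify_cv(ds, spec, seed) exactly
    fold_seed <- if (b == 1L) seed else stage_seed(seed, "boot-folds", b)
    out[[b]] <- classify_cv(ds_b, spec, seed = fold_seed)
  }
  out
}

#' Cumulative averages of conditional probability estimates
#'
#' Element `k` of the result is the element-wise mean of the
#' row-normalized first `k` confusion matrices.  The cumulative series
#' shows how quickly the conditional-probability structure (and any
#' similarity tree derived from it) stabilizes over repetitions.
#'
#' @param cms list of [confusion_matrix()] objects over a shared word
#'   set.
#' @return list of [cond_prob_matrix()] objects of the same length.
#' @export
cumulative_condprob <- function(cms) {
  if (!length(cms)) stop("need at least one confusion matrix")
  words <- word_labels(cms[[1L]])
  acc <- matrix(0, length(words), length(words),
                dimnames = list(as.character(words), as.character(words)))
  out <- vector("list", length(cms))
  for (k in seq_along(cms)) {
    p <- row_normalize(align_to_words(cms[[k]], words))
    acc <- acc + unclass(p)
    out[[k]] <- cond_prob_matrix(acc / k, words = as.character(words))
  }
  out
}
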