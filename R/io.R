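#' Read and write labeled square matrices
#'
#' The on-disk format is a plain CSV with a header row of word labels
#' (first cell empty) and the word labels repeated in the first column.
#' Values are written with 15 significant digits so that a
#' write-then-read round trip is lossless at any realistic precision.
#'
#' @param path file path.
#' @param kind what the values are: `"counts"` gives a
#'   [confusion_matrix()], `"probs"` a [cond_prob_matrix()], `"sims"` a
#'   [similarity_matrix()].  Each kind's invariants are validated on
#'   read, with errors naming the offending row.
#' @return the classed matrix.
#' @examples
#' p <- file.path(tempdir(), "counts.csv")
#' cm <- confusion_matrix(diag(5, 2), words = c("north", "south"))
#' write_labeled_matrix(cm, p)
#' read_labeled_matrix(p, "counts")
#' @export
read_labeled_matrix <- function(path, kind = c("counts", "probs", "sims")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("labeled matrix in ", path, " must be at least 2x2")
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square (", nrow(m), "x", ncol(m), ")")
  }
  if (!identical(labels, colnames(m))) {
    stop("row labels and column labels disagree in ", path)
  }
  rownames(m) <- labels
  switch(kind,
    counts = confusion_matrix(m),
    probs  = cond_prob_matrix(m),
    sims   = similarity_matrix(m)
  )
}

#' @rdname read_labeled_matrix
#' @param m a labeled square matrix (classed or plain with dimnames).
#' @export
write_labeled_matrix <- function(m, path) {
  if (is.null(rownames(m))) stop("matrix must carry word labels")
  df <- data.frame(format(unclass(m), digits = 15, scientific = FALSE,
                          trim = TRUE),
                   check.names = FALSE)
  df <- cbind(`""` = rownames(m), df)
  names(df)[1L] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
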