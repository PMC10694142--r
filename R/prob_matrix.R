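# Row-sum tolerance ladder: sums within .row_sum_clean of 1 are accepted
# as-is (covers the drift introduced by 10-significant-digit serialization,
# keeping write/read round-trips byte-stable), sums within .row_sum_tol are
# renormalised with a warning, anything beyond is an error.
.row_sum_clean <- 1e-9
.row_sum_tol <- 1e-6

#' Construct a validated class-probability matrix
#'
#' A probability matrix holds one row of class-membership probabilities per
#' sample, as emitted by a probabilistic classifier (e.g. a softmax layer).
#' Every entry must lie in `[0, 1]` and every row must sum to one. Rows whose
#' sum drifts from one by at most `1e-6` (common in floating-point score
#' exports) are renormalised with a warning; larger violations are errors.
#'
#' @param x numeric matrix or data frame of probabilities, samples in rows
#'   and classes in columns (at least two classes).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the row names of `x`, or `"s1".."sn"` when absent.
#' @param class_labels character vector of class names; defaults to the
#'   column names of `x`, or `"0","1",...` when absent.
#'
#' @return a numeric matrix of class `"prob_matrix"` with `sample_ids` as row
#'   names and `class_labels` as column names.
#' @examples
#' prob_matrix(rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'             sample_ids = c("a", "b"), class_labels = c("0", "1"))
#' @export
prob_matrix <- function(x, sample_ids = NULL, class_labels = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix or data frame of probabilities",
         call. = FALSE)
  if (ncol(x) < 2L)
    stop("a probability matrix needs at least two class columns", call. = FALSE)

  if (is.null(sample_ids)) sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  if (is.null(class_labels)) class_labels <- colnames(x)
  if (is.null(class_labels)) class_labels <- as.character(seq_len(ncol(x)) - 1L)
  sample_ids <- as.character(sample_ids)
  class_labels <- as.character(class_labels)

  if (length(sample_ids) != nrow(x))
    stop("length of `sample_ids` must equal the number of rows", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(class_labels) != ncol(x))
    stop("length of `class_labels` must equal the number of columns",
         call. = FALSE)

  dimnames(x) <- list(sample_ids, class_labels)
  .check_prob_entries(x)
  x <- .renormalize_rows(x)
  class(x) <- c("prob_matrix", class(x))
  x
}

# Entry-level validation with an error message naming the first offending
# sample and class.
.check_prob_entries <- function(x) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    i <- which(bad)[1L]
    r <- (i - 1L) %% nrow(x) + 1L
    c <- (i - 1L) %/% nrow(x) + 1L
    stop(sprintf(
      "invalid probability %s for sample '%s', class '%s' (must be finite and in [0, 1])",
      format(x[r, c]), rownames(x)[r], colnames(x)[c]), call. = FALSE)
  }
  invisible(x)
}

.renormalize_rows <- function(x) {
  s <- rowSums(x)
  dev <- abs(s - 1)
  if (any(dev > .row_sum_tol)) {
    r <- which.max(dev)
    stop(sprintf(
      "row %d (sample '%s') sums to %.8f; |sum - 1| exceeds tolerance %g",
      r, rownames(x)[r], s[r], .row_sum_tol), call. = FALSE)
  }
  drift <- dev > .row_sum_clean
  if (any(drift)) {
    warning(sprintf(
      "%d row(s) had probability sums off one by up to %.3g; renormalized",
      sum(drift), max(dev)), call. = FALSE)
    x[drift, ] <- x[drift, , drop = FALSE] / s[drift]
  }
  x
}

#' @export
print.prob_matrix <- function(x, ...) {
  cat(sprintf("Probability matrix: %d samples x %d classes (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  y <- x
  class(y) <- "matrix"
  print(utils::head(y, 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Coerce to prob_matrix unless already one (validation is idempotent but
# re-running it on trusted internal objects is wasteful).
.as_prob_matrix <- function(x) {
  if (inherits(x, "prob_matrix")) x else prob_matrix(x)
}

# Check that a list of probability matrices share sample ids (same order) and
# class labels; returns the list coerced to prob_matrix.
.check_aligned <- function(tables) {
  if (!is.list(tables) || length(tables) < 1L)
    stop("need a non-empty list of probability tables", call. = FALSE)
  tables <- lapply(tables, .as_prob_matrix)
  ref <- tables[[1L]]
  for (k in seq_along(tables)[-1L]) {
    t <- tables[[k]]
    if (!identical(rownames(t), rownames(ref)))
      stop(sprintf("classifier %d: sample identifiers do not match classifier 1",
                   k), call. = FALSE)
    if (!identical(colnames(t), colnames(ref)))
      stop(sprintf("classifier %d: class labels do not match classifier 1", k),
           call. = FALSE)
  }
  tables
}
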