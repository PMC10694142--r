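#' Confusion-matrix metrics for binary labels
#'
#' Standard definitions with `positive` the minority/event class (label
#' `"1"`, short-term survivor, by default): sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, accuracy
#' `(tp+tn)/total`, F1 the harmonic mean of precision and sensitivity, and
#' balanced accuracy the mean of sensitivity and specificity. A ratio with a
#' zero denominator is reported as 0 with a warning, so fold averages stay
#' finite.
#'
#' @param truth,predicted equal-length vectors of binary class labels; any
#'   atomic type, compared as characters. Both must take values in the
#'   two-level label set.
#' @param positive label of the positive class (default `"1"`).
#' @return object of class `"metrics_report"`: a list with confusion counts
#'   `tp`, `fp`, `tn`, `fn` and metrics `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `balanced_accuracy`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1))
#' @export
compute_metrics <- function(truth, predicted, positive = "1") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (length(truth) == 0L) stop("no samples to evaluate", call. = FALSE)
  lv <- unique(c(truth, predicted))
  if (length(lv) > 2L)
    stop("binary metrics need at most two label values, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (!positive %in% lv && length(lv) == 2L)
    stop(sprintf("positive class '%s' absent from labels (%s)", positive,
                 paste(lv, collapse = ", ")), call. = FALSE)

  pos_t <- truth == positive
  pos_p <- predicted == positive
  tp <- sum(pos_t & pos_p)
  fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p)
  tn <- sum(!pos_t & !pos_p)

  safe_ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", name),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sn <- safe_ratio(tp, tp + fn, "sensitivity")
  sp <- safe_ratio(tn, tn + fp, "specificity")
  prec <- safe_ratio(tp, tp + fp, "precision")
  ac <- (tp + tn) / length(truth)
  f1 <- if (prec + sn == 0) {
    warning("F1 undefined (precision + sensitivity = 0); reported as 0",
            call. = FALSE)
    0
  } else 2 * prec * sn / (prec + sn)

  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = ac, sensitivity = sn, specificity = sp, precision = prec,
    f1 = f1, balanced_accuracy = (sn + sp) / 2,
    positive = positive, n = length(truth)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Binary classification metrics (n = %d, positive = '%s')\n",
              x$n, x$positive))
  cat(sprintf("  confusion: tp %d  fp %d  tn %d  fn %d\n",
              x$tp, x$fp, x$tn, x$fn))
  m <- unlist(x[c("accuracy", "sensitivity", "specificity", "precision",
                  "f1", "balanced_accuracy")])
  print(round(m, 4))
  invisible(x)
}

#' Stratified fold assignment for cross-validation
#'
#' Within each class, samples are shuffled (reproducibly from `seed`) and
#' dealt round-robin across the `k` folds, so per-class fold counts differ
#' from exact proportionality by at most one sample. Suited to imbalanced
#' cohorts where every fold must contain a representative share of the
#' minority class.
#'
#' @param labels vector of class labels, one per sample.
#' @param k number of folds (default 10).
#' @param seed integer seed; the same seed always yields the same
#'   assignment, and the caller's RNG state is left untouched.
#' @return integer vector of fold indices in `1..k`, one per sample, with
#'   attributes `k` and `seed`.
#' @examples
#' table(stratified_folds(rep(c(0, 1), c(40, 10)), k = 5, seed = 1),
#'       rep(c(0, 1), c(40, 10)))
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop(sprintf(
      "class '%s' has %d samples, fewer than k = %d folds",
      names(tab)[which.min(tab)], min(tab), k), call. = FALSE)

  fold <- integer(length(labels))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  for (cls in names(tab)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(fold, k = k, seed = as.integer(seed))
}

#' Cross-validated evaluation of the deviation-support ensemble
#'
#' Runs the fused predictor fold by fold: for each fold, the ensemble is
#' applied to that fold's test samples and scored against the true labels;
#' metrics are averaged (unweighted) across folds. The score tables are
#' expected to hold out-of-fold probabilities, i.e. each sample's row was
#' produced by base classifiers not trained on that sample.
#'
#' Classifier accuracies feeding the fuzzy densities follow
#' `accuracy_policy`:
#' \describe{
#'   \item{"out-of-fold"}{(default) for each fold, every classifier's
#'     accuracy is computed from its own argmax predictions on the
#'     *training* portion (all samples outside the test fold), so no test
#'     label leaks into the measure.}
#'   \item{"manifest"}{the fixed `accuracies` vector is used for every
#'     fold (e.g. accuracies reported with externally trained models).}
#' }
#'
#' @param scores list of probability tables covering all samples, one per
#'   classifier.
#' @param labels true class labels, aligned with the tables' rows.
#' @param k,seed fold count and shuffling seed (used when `folds` is
#'   missing).
#' @param folds optional precomputed assignment from [stratified_folds()].
#' @param accuracies fixed per-classifier accuracies (required for policy
#'   `"manifest"`).
#' @param accuracy_policy `"out-of-fold"` or `"manifest"`.
#' @param positive positive class label for the metrics.
#' @return object of class `"dsfuse_cv"`: list with `per_fold` (data frame
#'   of per-fold metrics), `mean` (named numeric vector, unweighted fold
#'   mean), `folds`, and `agreement_rate` (overall pathway agreement).
#' @export
cross_validate_ensemble <- function(scores, labels, k = 10L, seed = 1L,
                                    folds = NULL, accuracies = NULL,
                                    accuracy_policy = c("out-of-fold",
                                                        "manifest"),
                                    positive = "1") {
  accuracy_policy <- match.arg(accuracy_policy)
  tables <- .check_aligned(scores)
  labels <- as.character(labels)
  n <- nrow(tables[[1L]])
  if (length(labels) != n)
    stop(sprintf("%d labels for %d samples", length(labels), n), call. = FALSE)
  if (accuracy_policy == "manifest" && is.null(accuracies))
    stop("accuracy_policy = 'manifest' requires `accuracies`", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(labels, k = k, seed = seed)
  if (length(folds) != n)
    stop("fold assignment does not cover all samples", call. = FALSE)
  k <- max(folds)

  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1", "balanced_accuracy")
  per_fold <- matrix(NA_real_, k, length(metric_names),
                     dimnames = list(NULL, metric_names))
  agreed <- logical(n)

  for (f in seq_len(k)) {
    test <- folds == f
    acc_f <- if (accuracy_policy == "manifest") {
      accuracies
    } else {
      vapply(tables, function(t) {
        pred <- colnames(t)[max.col(t[!test, , drop = FALSE],
                                    ties.method = "first")]
        mean(pred == labels[!test])
      }, numeric(1))
    }
    fit <- dsfuse(lapply(tables, function(t) t[test, , drop = FALSE]),
                  accuracies = acc_f, relevance = FALSE)
    rep <- compute_metrics(labels[test], fit$labels, positive = positive)
    per_fold[f, ] <- unlist(rep[metric_names])
    agreed[test] <- fit$decisions$agreed
  }

  per_fold <- as.data.frame(per_fold)
  per_fold <- cbind(fold = seq_len(k), per_fold)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_names]),
    folds = folds,
    agreement_rate = mean(agreed),
    accuracy_policy = accuracy_policy
  ), class = "dsfuse_cv")
}

#' @export
print.dsfuse_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated deviation-support ensemble (accuracy policy: %s)\n",
              nrow(x$per_fold), x$accuracy_policy))
  cat("Fold means:\n")
  print(round(x$mean, 4))
  cat(sprintf("Pathway agreement rate: %.2f%%\n", 100 * x$agreement_rate))
  invisible(x)
}

#' Weighted-average ensemble baseline
#'
#' The classical fixed-weight fusion: each classifier's probability row is
#' multiplied by its weight and the weighted rows are summed; the predicted
#' class is the argmax of the fused probabilities (ties toward the lowest
#' class index). Weights are renormalised to sum to one.
#'
#' @param scores list of aligned probability tables, one per classifier.
#' @param weights non-negative weights, one per classifier, not all zero.
#'   Defaults to equal weights.
#' @return character vector of predicted class labels, named by sample id.
#' @export
weighted_average_baseline <- function(scores, weights = NULL) {
  tables <- .check_aligned(scores)
  C <- length(tables)
  if (is.null(weights)) weights <- rep(1, C)
  if (length(weights) != C)
    stop(sprintf("%d weights for %d classifiers", length(weights), C),
         call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (sum(weights) == 0)
    stop("weights must not all be zero", call. = FALSE)
  weights <- weights / sum(weights)

  fused <- 0
  for (c in seq_len(C)) fused <- fused + weights[c] * unclass(tables[[c]])
  lab <- colnames(fused)[max.col(fused, ties.method = "first")]
  stats::setNames(lab, rownames(fused))
}
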