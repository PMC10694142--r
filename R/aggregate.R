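#' Choquet integral of per-classifier scores
#'
#' Aggregates one score per classifier against a Sugeno lambda fuzzy
#' measure. Values are sorted in descending order (ties broken by ascending
#' classifier index); with `v[1] >= v[2] >= ... >= v[C]` the sorted values
#' and `A_k` the set of the top-`k` classifiers, the integral is
#' `sum_k (v[k] - v[k+1]) * g(A_k)` with `v[C+1] = 0`. When the measure is
#' additive (`lambda = 0`) this reduces to the density-weighted mean. The
#' integral is idempotent: equal inputs return that common value.
#'
#' @param values numeric vector, one finite score in `[0, 1]` per classifier.
#' @param measure a [lambda_measure()] over the same number of classifiers.
#' @return scalar aggregated score.
#' @examples
#' m <- lambda_measure(densities = c(0.5, 0.5))
#' choquet_integral(c(0.3, 0.1), m)  # 0.2, the weighted mean
#' @export
choquet_integral <- function(values, measure) {
  stopifnot(inherits(measure, "lambda_measure"))
  v <- as.numeric(values)
  if (length(v) != length(measure$densities))
    stop(sprintf("got %d values for a measure over %d classifiers",
                 length(v), length(measure$densities)), call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop("values must be finite and in [0, 1]", call. = FALSE)
  drop(.choquet_rows(matrix(v, nrow = 1L), measure))
}

# Vectorised Choquet integral: one integral per row of V, all rows sharing
# the same measure. Sort each row descending (ties by ascending column) with
# a single order() call, then fold the subset measure along the sorted
# prefix via g(A + j) = g(A) + g_j + lambda g(A) g_j.
.choquet_rows <- function(V, measure) {
  n <- nrow(V)
  C <- ncol(V)
  g <- measure$densities
  lam <- measure$lambda
  if (C == 1L) return(V[, 1L] * g[1L])

  o <- order(row(V), -V, col(V))
  Vs <- matrix(V[o], nrow = n, byrow = TRUE)            # sorted values
  gs <- matrix(g[col(V)[o]], nrow = n, byrow = TRUE)    # densities in sorted order

  out <- numeric(n)
  G <- gs[, 1L]                                         # g of top-1 subset
  for (k in seq_len(C)) {
    vnext <- if (k < C) Vs[, k + 1L] else 0
    out <- out + (Vs[, k] - vnext) * G
    if (k < C) {
      gj <- gs[, k + 1L]
      G <- G + gj + lam * G * gj
    }
  }
  out
}

#' Aggregate deviation and support scores across classifiers
#'
#' Applies the Choquet integral independently to the per-classifier
#' deviation scores and support scores, for every sample and class. The
#' aggregated deviation lies in `[0, 1 - exp(-1/2)]` and the aggregated
#' support in `[1 - tanh(1/2), 1]`, since a Choquet integral with a
#' normalised measure stays within the convex hull of its inputs.
#'
#' @param transformed list of [transform_scores()] results (or of
#'   probability tables, which are transformed on the fly), one per
#'   classifier, aligned on samples and classes.
#' @param measure a [lambda_measure()] over the classifiers.
#' @return list of class `"aggregated_scores"` with matrices `deviation`
#'   and `support` (samples x classes).
#' @export
aggregate_per_class <- function(transformed, measure) {
  stopifnot(inherits(measure, "lambda_measure"))
  if (!is.list(transformed) || length(transformed) < 1L)
    stop("need a non-empty list of transformed scores", call. = FALSE)
  if (!all(vapply(transformed, inherits, logical(1), "transformed_scores"))) {
    transformed <- lapply(.check_aligned(transformed), transform_scores)
  }
  C <- length(transformed)
  if (C != length(measure$densities))
    stop(sprintf("%d classifiers but measure over %d", C,
                 length(measure$densities)), call. = FALSE)
  ref <- transformed[[1L]]$deviation
  for (t in transformed[-1L]) {
    if (!identical(dim(t$deviation), dim(ref)))
      stop("transformed score matrices are not aligned", call. = FALSE)
  }
  n <- nrow(ref); N <- ncol(ref)

  dev_agg <- matrix(NA_real_, n, N, dimnames = dimnames(ref))
  sup_agg <- matrix(NA_real_, n, N, dimnames = dimnames(ref))
  for (j in seq_len(N)) {
    Dj <- vapply(transformed, function(t) t$deviation[, j], numeric(n))
    Sj <- vapply(transformed, function(t) t$support[, j], numeric(n))
    if (n == 1L) { Dj <- matrix(Dj, 1L); Sj <- matrix(Sj, 1L) }
    dev_agg[, j] <- .choquet_rows(Dj, measure)
    sup_agg[, j] <- .choquet_rows(Sj, measure)
  }
  structure(list(deviation = dev_agg, support = sup_agg),
            class = "aggregated_scores")
}

#' Final labels from aggregated deviation and support
#'
#' The deviation pathway proposes the class with the smallest aggregated
#' deviation; the support pathway proposes the class with the largest
#' aggregated support (ties broken toward the lowest class index in both).
#' When the two agree, that class is the prediction; on a clash the
#' deviation pathway wins, so the final label always equals
#' `argmin` of the aggregated deviation. The per-sample agreement flag is
#' retained as a diagnostic.
#'
#' @param agg an `"aggregated_scores"` object from [aggregate_per_class()].
#' @return data frame with one row per sample: `sample_id`, `label`
#'   (predicted class label), `agreed` (logical), `deviation_choice`,
#'   `support_choice` (class labels proposed by each pathway).
#' @export
decide_labels <- function(agg) {
  stopifnot(inherits(agg, "aggregated_scores"))
  D <- agg$deviation; S <- agg$support
  if (any(!is.finite(D)) || any(!is.finite(S)))
    stop("aggregated scores contain non-finite values", call. = FALSE)
  dev_idx <- apply(D, 1L, which.min)   # which.min/max break ties low
  sup_idx <- apply(S, 1L, which.max)
  labels <- colnames(D)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(D)) - 1L)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(D)))
  data.frame(
    sample_id = ids,
    label = labels[dev_idx],
    agreed = dev_idx == sup_idx,
    deviation_choice = labels[dev_idx],
    support_choice = labels[sup_idx],
    stringsAsFactors = FALSE,
    row.names = NULL)
}
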