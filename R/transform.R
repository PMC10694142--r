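#' Deviation and support transforms of prediction probabilities
#'
#' Two non-linear transforms map a predicted class probability `p` onto a
#' penalty and a reward for that class:
#'
#' * deviation `D = 1 - exp(-(p - 1)^2 / 2)` — how far the prediction falls
#'   from full confidence in the class; strictly decreasing in `p`, with
#'   range `[0, 1 - exp(-1/2)]` (about 0.3935 at `p = 0`).
#' * support `S = 1 - tanh((p - 1)^2 / 2)` — how close the prediction is to
#'   full confidence; strictly increasing in `p`, with range
#'   `[1 - tanh(1/2), 1]` (about 0.5379 at `p = 0`).
#'
#' The deviation range lies entirely below the support range, so a product
#' of the two is dominated by the deviation term; this range dominance is
#' the rationale for preferring the deviation pathway when the two
#' aggregated pathways disagree (see [decide_labels()]).
#'
#' @param probs a [prob_matrix()], or any numeric vector/matrix of
#'   probabilities in `[0, 1]` (a bare vector or non-row-stochastic matrix is
#'   transformed elementwise without row-sum validation).
#' @return numeric object of the same shape as `probs` holding the
#'   transformed scores.
#' @examples
#' support_scores(c(0, 0.5, 1))    # 0.5379, 0.8756, 1
#' deviation_scores(c(0, 0.5, 1))  # 0.3935, 0.1175, 0
#' @seealso [transform_scores()] for both pathways at once,
#'   [multiplicative_relevance()] for the product diagnostic.
#' @export
support_scores <- function(probs) {
  p <- .transform_input(probs)
  1 - tanh((p - 1)^2 / 2)
}

#' @rdname support_scores
#' @export
deviation_scores <- function(probs) {
  p <- .transform_input(probs)
  1 - exp(-(p - 1)^2 / 2)
}

.transform_input <- function(probs) {
  if (inherits(probs, "prob_matrix")) {
    p <- unclass(probs)
  } else {
    if (!is.numeric(probs))
      stop("`probs` must be numeric", call. = FALSE)
    p <- probs
    bad <- !is.finite(p) | p < 0 | p > 1
    if (any(bad)) {
      if (is.matrix(p) && !is.null(dimnames(p))) {
        i <- which(bad)[1L]
        r <- (i - 1L) %% nrow(p) + 1L
        c <- (i - 1L) %/% nrow(p) + 1L
        stop(sprintf(
          "invalid probability %s for sample '%s', class '%s'",
          format(p[r, c]), rownames(p)[r], colnames(p)[c]), call. = FALSE)
      }
      stop(sprintf("invalid probability %s at position %d (must be finite, in [0, 1])",
                   format(p[which(bad)[1L]]), which(bad)[1L]), call. = FALSE)
    }
  }
  p
}

#' Deviation and support scores for one classifier
#'
#' @param probs a [prob_matrix()] (or coercible) of one classifier's
#'   class probabilities.
#' @return list of class `"transformed_scores"` with elements `deviation`
#'   and `support`, matrices of the same shape as `probs`.
#' @export
transform_scores <- function(probs) {
  probs <- .as_prob_matrix(probs)
  structure(
    list(deviation = deviation_scores(probs),
         support = support_scores(probs)),
    class = "transformed_scores")
}

#' Multiplicative deviation-support relevance (diagnostic)
#'
#' For each sample and class, sums the product of deviation and support
#' scores over classifiers: `R_n = sum_c D^c_n * S^c_n`. Because the
#' deviation range lies below the support range, the product is dominated
#' by the deviation term; the quantity is reported as a diagnostic
#' illustrating why the decision rule prefers the deviation pathway. It
#' never drives the predicted label.
#'
#' @param tables list of aligned probability tables (one per classifier),
#'   each a [prob_matrix()] or coercible.
#' @return numeric matrix (samples x classes) of relevance values.
#' @export
multiplicative_relevance <- function(tables) {
  tables <- .check_aligned(tables)
  r <- 0
  for (t in tables) {
    r <- r + deviation_scores(t) * support_scores(t)
  }
  r
}
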