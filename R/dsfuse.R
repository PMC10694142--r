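#' Fit a deviation-support fuzzy ensemble
#'
#' Fuses the class-probability outputs of `C` base classifiers into one
#' prediction per sample. The pipeline is: (1) map each probability to a
#' deviation (penalty) and a support (reward) score; (2) build a Sugeno
#' lambda fuzzy measure over classifier subsets from the classifier
#' accuracies (densities `g_i = acc_i / sum(acc)`); (3) aggregate the
#' per-class deviation and support scores across classifiers with the
#' Choquet integral; (4) predict the class minimising the aggregated
#' deviation, preferring the deviation pathway whenever the support pathway
#' (argmax of aggregated support) disagrees.
#'
#' Because the densities are accuracy-normalised they sum to one, the solved
#' lambda is zero, and the Choquet aggregation reduces to an
#' accuracy-weighted mean of the transformed scores; the general non-additive
#' path is exercised whenever unnormalised densities are supplied through
#' `measure`.
#'
#' @param scores list of probability tables, one per classifier, aligned on
#'   samples and classes; each a [prob_matrix()] or coercible matrix/data
#'   frame.
#' @param accuracies numeric vector of classifier accuracies in `(0, 1]`,
#'   length `C`, used to build the fuzzy measure. Ignored when `measure` is
#'   given.
#' @param measure optional [lambda_measure()] to use instead of one built
#'   from `accuracies`.
#' @param relevance logical; also compute the multiplicative
#'   deviation-support diagnostic ([multiplicative_relevance()])?
#' @return object of class `"dsfuse"` with components:
#'   \describe{
#'     \item{labels}{character vector of predicted class labels per sample}
#'     \item{decisions}{data frame from [decide_labels()] with agreement
#'       diagnostics}
#'     \item{deviation, support}{aggregated score matrices (samples x
#'       classes)}
#'     \item{relevance}{diagnostic matrix or `NULL`}
#'     \item{measure}{the [lambda_measure()] used}
#'     \item{class_labels, sample_ids, n_classifiers}{bookkeeping}
#'   }
#' @examples
#' p1 <- prob_matrix(rbind(c(0.9, 0.1), c(0.4, 0.6)),
#'                   sample_ids = c("a", "b"), class_labels = c("0", "1"))
#' p2 <- prob_matrix(rbind(c(0.7, 0.3), c(0.2, 0.8)),
#'                   sample_ids = c("a", "b"), class_labels = c("0", "1"))
#' fit <- dsfuse(list(p1, p2), accuracies = c(0.8, 0.75))
#' fitted(fit)
#' summary(fit)
#' @seealso [cross_validate_ensemble()] for the k-fold harness,
#'   [weighted_average_baseline()] for the fixed-weight baseline.
#' @export
dsfuse <- function(scores, accuracies = NULL, measure = NULL,
                   relevance = TRUE) {
  cl <- match.call()
  tables <- .check_aligned(scores)
  C <- length(tables)
  if (is.null(measure)) {
    if (is.null(accuracies))
      stop("supply `accuracies` (length one per classifier) or a `measure`",
           call. = FALSE)
    if (length(accuracies) != C)
      stop(sprintf("%d accuracies for %d classifiers", length(accuracies), C),
           call. = FALSE)
    measure <- lambda_measure(accuracies = accuracies)
  } else {
    stopifnot(inherits(measure, "lambda_measure"))
    if (length(measure$densities) != C)
      stop(sprintf("measure over %d classifiers but %d score tables supplied",
                   length(measure$densities), C), call. = FALSE)
  }

  transformed <- lapply(tables, transform_scores)
  agg <- aggregate_per_class(transformed, measure)
  decisions <- decide_labels(agg)

  .log_info("fuzzy densities: %s; lambda = %s; agreement rate = %.4f",
            paste(formatC(measure$densities, digits = 6, format = "g"),
                  collapse = ", "),
            formatC(measure$lambda, digits = 6, format = "g"),
            mean(decisions$agreed))

  structure(list(
    call = cl,
    labels = decisions$label,
    decisions = decisions,
    deviation = agg$deviation,
    support = agg$support,
    relevance = if (isTRUE(relevance)) multiplicative_relevance(tables) else NULL,
    measure = measure,
    class_labels = colnames(tables[[1L]]),
    sample_ids = rownames(tables[[1L]]),
    n_classifiers = C
  ), class = "dsfuse")
}

#' @export
print.dsfuse <- function(x, ...) {
  cat("Deviation-support fuzzy ensemble\n")
  cat(sprintf("  %d classifiers, %d samples, classes: %s\n",
              x$n_classifiers, length(x$labels),
              paste(x$class_labels, collapse = ", ")))
  cat("  densities:", paste(formatC(x$measure$densities, digits = 4,
                                    format = "g"), collapse = ", "), "\n")
  cat(sprintf("  lambda: %s   pathway agreement: %.1f%%\n",
              formatC(x$measure$lambda, digits = 4, format = "g"),
              100 * mean(x$decisions$agreed)))
  cat("  predicted label counts:\n")
  print(table(factor(x$labels, levels = x$class_labels)))
  invisible(x)
}

#' @export
fitted.dsfuse <- function(object, ...) {
  stats::setNames(object$labels, object$sample_ids)
}

#' @export
summary.dsfuse <- function(object, ...) {
  s <- list(
    n_classifiers = object$n_classifiers,
    n_samples = length(object$labels),
    class_labels = object$class_labels,
    densities = object$measure$densities,
    lambda = object$measure$lambda,
    agreement_rate = mean(object$decisions$agreed),
    label_counts = table(factor(object$labels, levels = object$class_labels)),
    deviation_range = range(object$deviation),
    support_range = range(object$support))
  class(s) <- "summary.dsfuse"
  s
}

#' @export
print.summary.dsfuse <- function(x, ...) {
  cat("Deviation-support fuzzy ensemble\n")
  cat(sprintf("  classifiers: %d   samples: %d\n", x$n_classifiers,
              x$n_samples))
  cat("  densities g_i:", paste(formatC(x$densities, digits = 6,
                                        format = "g"), collapse = ", "), "\n")
  cat(sprintf("  lambda: %s%s\n",
              formatC(x$lambda, digits = 6, format = "g"),
              if (x$lambda == 0) " (additive: Choquet = weighted mean)" else ""))
  cat(sprintf("  deviation/support pathway agreement: %.2f%%\n",
              100 * x$agreement_rate))
  cat(sprintf("  aggregated deviation in [%.4f, %.4f], support in [%.4f, %.4f]\n",
              x$deviation_range[1], x$deviation_range[2],
              x$support_range[1], x$support_range[2]))
  cat("  predicted label counts:\n")
  print(x$label_counts)
  invisible(x)
}

#' Predict from a fitted deviation-support ensemble
#'
#' Applies the fitted ensemble's fuzzy measure to new probability tables
#' from the same classifiers.
#'
#' @param object a fitted [dsfuse()] object.
#' @param newdata list of probability tables (one per classifier, in the
#'   same order as at fit time); defaults to returning the fitted labels.
#' @param type `"label"` for predicted class labels, `"deviation"` or
#'   `"support"` for the aggregated score matrices, `"decisions"` for the
#'   full decision data frame.
#' @param ... unused.
#' @return per `type`: character vector, numeric matrix, or data frame.
#' @export
predict.dsfuse <- function(object, newdata = NULL,
                           type = c("label", "deviation", "support",
                                    "decisions"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    res <- object
  } else {
    res <- dsfuse(newdata, measure = object$measure, relevance = FALSE)
  }
  switch(type,
         label = stats::setNames(res$labels, res$sample_ids),
         deviation = res$deviation,
         support = res$support,
         decisions = res$decisions)
}

#' Plot aggregated deviation against aggregated support
#'
#' One point per sample for a chosen class: the aggregated deviation on the
#' x axis and aggregated support on the y axis. Samples where the two
#' pathways disagreed are drawn as open triangles. Since both transforms are
#' monotone in the underlying probability, points fall on a decreasing
#' curve; clashes concentrate where classifiers disagree.
#'
#' @param x a fitted [dsfuse()] object.
#' @param class_label class (column) to display; defaults to the first.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dsfuse <- function(x, class_label = x$class_labels[1L], ...) {
  j <- match(class_label, x$class_labels)
  if (is.na(j)) stop("unknown class label: ", class_label, call. = FALSE)
  agreed <- x$decisions$agreed
  graphics::plot(x$deviation[, j], x$support[, j],
                 pch = ifelse(agreed, 16L, 2L),
                 col = ifelse(agreed, "grey30", "red3"),
                 xlab = sprintf("aggregated deviation (class %s)", class_label),
                 ylab = sprintf("aggregated support (class %s)", class_label),
                 ...)
  graphics::legend("topright", pch = c(16L, 2L), col = c("grey30", "red3"),
                   legend = c("pathways agree", "clash (deviation wins)"),
                   bty = "n")
  invisible(x)
}

# Lightweight INFO logging; suppress with options(dsfuse.quiet = TRUE).
.log_info <- function(fmt, ...) {
  if (!isTRUE(getOption("dsfuse.quiet", FALSE)))
    message(sprintf(paste0("[dsfuse] ", fmt), ...))
  invisible(NULL)
}
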