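#' Fuzzy densities from classifier accuracies
#'
#' The importance (fuzzy density) of classifier `i` is its accuracy
#' normalised by the sum of all classifier accuracies:
#' `g_i = acc_i / sum(acc)`. The densities therefore always sum to one,
#' which makes the induced Sugeno lambda measure additive (`lambda = 0`);
#' see [solve_lambda()].
#'
#' @param accuracies numeric vector of classifier accuracies, each in
#'   `(0, 1]`.
#' @return numeric vector of densities summing to one, with
#'   `attr(, "accuracies")` carrying the source accuracies.
#' @examples
#' densities_from_accuracies(c(0.7727, 0.7717, 0.8182, 0.8187))
#' @export
densities_from_accuracies <- function(accuracies) {
  if (length(accuracies) < 1L)
    stop("need at least one accuracy", call. = FALSE)
  if (!is.numeric(accuracies) || any(!is.finite(accuracies)))
    stop("accuracies must be finite numbers", call. = FALSE)
  if (any(accuracies <= 0) || any(accuracies > 1))
    stop("accuracies must lie in (0, 1]", call. = FALSE)
  g <- accuracies / sum(accuracies)
  attr(g, "accuracies") <- as.numeric(accuracies)
  g
}

#' Solve for the Sugeno lambda parameter
#'
#' The lambda measure built from densities `g_i` requires the parameter
#' `lambda` in `(-1, Inf)` solving `1 + lambda = prod(g_i * lambda + 1)`.
#' `lambda = 0` is a root for any densities; it is the measure-consistent
#' root exactly when the densities sum to one (the measure is then
#' additive). Otherwise the unique non-zero root is returned: positive when
#' `sum(g) < 1`, in `(-1, 0)` when `sum(g) > 1`. The root is found by
#' bracketed bisection/Newton refinement to a residual below `1e-12`.
#'
#' @param densities numeric vector of non-negative densities (length
#'   `C >= 1`), e.g. from [densities_from_accuracies()].
#' @return scalar lambda.
#' @examples
#' solve_lambda(c(0.5, 0.5))   # 0 (additive)
#' solve_lambda(c(0.2, 0.3))   # 25/3
#' solve_lambda(c(0.6, 0.6))   # -5/9
#' @export
solve_lambda <- function(densities) {
  g <- as.numeric(densities)
  if (length(g) < 1L || any(!is.finite(g)) || any(g < 0))
    stop("densities must be non-negative finite numbers", call. = FALSE)
  s <- sum(g)
  if (abs(s - 1) <= 1e-12) return(0)
  if (length(g) == 1L)
    stop(sprintf(
      "a single density must equal 1 to define a measure (got %g)", g),
      call. = FALSE)
  if (sum(g > 0) < 2L)
    stop("need at least two positive densities when they do not sum to 1",
         call. = FALSE)

  # residual of the defining equation; f(0) = 0 always, we want the other
  # root, so both bracket endpoints are kept well away from 0 (the residual
  # is O(eps) near 0 and a bracketed solver would happily return it)
  f <- function(l) prod(g * l + 1) - (1 + l)
  if (s < 1) {
    # root in (0, Inf): f < 0 on (0, root), f -> +Inf as l -> Inf
    lo <- 1
    while (f(lo) >= 0 && lo > 1e-13) lo <- lo / 2
    hi <- max(2 * lo, 1)
    while (f(hi) < 0) {
      hi <- hi * 2
      if (hi > 1e12)
        stop("failed to bracket lambda root (sum of densities ", format(s),
             ")", call. = FALSE)
    }
  } else {
    # root in (-1, 0): f >= 0 on (-1, root], f < 0 on (root, 0)
    lo <- -1 + 1e-12
    if (f(lo) < 0)
      stop("failed to bracket lambda root in (-1, 0) (sum of densities ",
           format(s), ")", call. = FALSE)
    hi <- -0.5
    while (f(hi) >= 0 && hi < -1e-13) {
      lo <- hi
      hi <- hi / 2
    }
  }
  root <- stats::uniroot(f, lower = lo, upper = hi,
                         tol = .Machine$double.eps^0.75)$root
  # Newton polish to push the residual to ~1e-15
  for (i in 1:8) {
    fr <- f(root)
    if (abs(fr) <= 1e-13) break
    dfr <- sum(g / (g * root + 1)) * prod(g * root + 1) - 1
    if (!is.finite(dfr) || dfr == 0) break
    step <- fr / dfr
    cand <- root - step
    if (cand <= -1) break
    root <- cand
  }
  if (abs(f(root)) > 1e-12)
    stop(sprintf("lambda root refinement did not converge (residual %.3g)",
                 f(root)), call. = FALSE)
  root
}

#' Sugeno lambda fuzzy measure over classifier subsets
#'
#' Builds the non-additive set function `g(A)` over subsets of classifiers
#' from per-classifier densities: `g({i}) = g_i`, and subsets combine via
#' `g(A U {j}) = g(A) + g_j + lambda * g(A) * g_j`, with `g(empty) = 0` and
#' `g(full set) = 1`. Supply either `densities` directly or classifier
#' `accuracies` (converted with [densities_from_accuracies()], which yields
#' the additive case `lambda = 0`).
#'
#' @param densities numeric vector of non-negative densities.
#' @param accuracies numeric vector of accuracies in `(0, 1]`; used when
#'   `densities` is missing.
#' @return object of class `"lambda_measure"` with elements `densities` and
#'   `lambda`.
#' @examples
#' m <- lambda_measure(accuracies = c(0.7727, 0.7717, 0.8182, 0.8187))
#' measure_of_subset(m, 1:4)  # 1
#' @export
lambda_measure <- function(densities = NULL, accuracies = NULL) {
  if (is.null(densities)) {
    if (is.null(accuracies))
      stop("supply `densities` or `accuracies`", call. = FALSE)
    densities <- densities_from_accuracies(accuracies)
  }
  g <- as.numeric(densities)
  lam <- solve_lambda(g)
  structure(list(densities = g, lambda = lam), class = "lambda_measure")
}

#' @export
print.lambda_measure <- function(x, ...) {
  cat(sprintf("Sugeno lambda fuzzy measure over %d classifiers\n",
              length(x$densities)))
  cat("  densities:", paste(formatC(x$densities, digits = 6, format = "g"),
                            collapse = ", "), "\n")
  cat(sprintf("  lambda: %s%s\n", formatC(x$lambda, digits = 6, format = "g"),
              if (x$lambda == 0) " (additive measure)" else ""))
  invisible(x)
}

#' Measure of a subset of classifiers
#'
#' Evaluates `g(A)` by left-folding the pairwise combination rule
#' `g(A U {j}) = g(A) + g_j + lambda * g(A) * g_j` over the members of `A`
#' in increasing index order. The empty set has measure 0 exactly; the full
#' set has measure 1 (up to roundoff) when lambda was solved from the
#' densities. The fold is order-independent.
#'
#' @param measure a [lambda_measure()].
#' @param subset integer vector of classifier indices in `1..C` (may be
#'   empty; duplicates are an error).
#' @return scalar `g(A)`.
#' @export
measure_of_subset <- function(measure, subset) {
  stopifnot(inherits(measure, "lambda_measure"))
  g <- measure$densities
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(0)
  if (anyDuplicated(subset))
    stop("subset contains duplicate indices", call. = FALSE)
  if (any(subset < 1L | subset > length(g)))
    stop(sprintf("classifier index out of range 1..%d", length(g)),
         call. = FALSE)
  subset <- sort(subset)
  acc <- g[subset[1L]]
  for (j in subset[-1L]) {
    acc <- acc + g[j] + measure$lambda * acc * g[j]
  }
  if (acc < -1e-12)
    stop(sprintf("measure of subset evaluated negative (%.3g); densities invalid",
                 acc), call. = FALSE)
  acc
}
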