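# Scale of the baseline Dirichlet concentration (prior * .conc_scale). Large
# enough that a zero-quality classifier behaves like a majority-class guesser
# (its scores hug the class prior); the quality boost on the true class then
# moves accuracy from max(prior) toward 1. The boost at which the minority
# class becomes detectable (sensitivity 0.5) is .conc_scale * (p_maj - p_min).
.conc_scale <- 20

#' Configuration for the synthetic score simulator
#'
#' Defaults emulate an imbalanced binary survival cohort scored by four base
#' classifiers of unequal quality: 1980 samples with class prior 1489:491
#' (long- vs short-term survivors), and quality boosts chosen so that under
#' conditional independence every classifier's sensitivity for the minority
#' class sits above 0.5 (the weakest around 0.53, like realistic trained
#' base classifiers on such a cohort) with expected accuracies spread over
#' roughly 0.88-0.93.
#'
#' @param n_samples cohort size.
#' @param class_prior probability vector over the `N` classes (sums to 1).
#' @param n_classifiers number of base classifiers `C`.
#' @param quality non-negative vector (recycled to length `C`): Dirichlet
#'   concentration added to the true class; 0 gives a classifier whose
#'   scores are label-free draws around the prior, large values give a
#'   near-perfect classifier.
#' @param miscalibration positive vector (recycled): temperature applied to
#'   each classifier's probability rows (`p^(1/T)`, renormalised); `T > 1`
#'   flattens scores, `T < 1` sharpens them. Leaves the argmax, hence
#'   accuracy, unchanged.
#' @param correlation in `[0, 1)`: weight of a latent per-sample noise
#'   component shared by all classifiers; 0 makes classifiers conditionally
#'   independent given the label.
#' @param class_labels character labels for the classes.
#' @param seed integer seed making the cohort reproducible.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples = 1980L,
                              class_prior = c(1489, 491) / 1980,
                              n_classifiers = 4L,
                              quality = c(10.5, 11, 12.5, 13),
                              miscalibration = 1,
                              correlation = 0,
                              class_labels = as.character(
                                seq_along(class_prior) - 1L),
                              seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_classifiers <- as.integer(n_classifiers)
  if (n_samples < 1L || n_classifiers < 1L)
    stop("n_samples and n_classifiers must be positive", call. = FALSE)
  if (length(class_prior) < 2L || any(class_prior < 0) ||
      abs(sum(class_prior) - 1) > 1e-8)
    stop("class_prior must be a probability vector over >= 2 classes",
         call. = FALSE)
  if (any(!is.finite(quality)) || any(quality < 0))
    stop("quality boosts must be non-negative", call. = FALSE)
  if (any(!is.finite(miscalibration)) || any(miscalibration <= 0))
    stop("miscalibration temperatures must be positive", call. = FALSE)
  if (length(correlation) != 1L || !is.finite(correlation) ||
      correlation < 0 || correlation >= 1)
    stop("correlation must be a single value in [0, 1)", call. = FALSE)
  if (length(class_labels) != length(class_prior))
    stop("one class label per prior entry required", call. = FALSE)

  structure(list(
    n_samples = n_samples,
    class_prior = as.numeric(class_prior),
    n_classifiers = n_classifiers,
    quality = rep_len(as.numeric(quality), n_classifiers),
    miscalibration = rep_len(as.numeric(miscalibration), n_classifiers),
    correlation = as.numeric(correlation),
    class_labels = as.character(class_labels),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate an imbalanced cohort scored by several classifiers
#'
#' Generates true labels from the class prior, then per-classifier
#' probability tables from a Dirichlet-type mechanism: each sample has a
#' concentration vector `alpha = 20 * prior + quality * onehot(true class)`;
#' independent Gamma(alpha) draws are made once per sample (the shared,
#' latent component) and once per classifier, mixed as
#' `correlation * shared + (1 - correlation) * own`, and normalised to a
#' probability row. Rows are then temperature-scaled by `miscalibration`
#' and renormalised. Higher `quality` concentrates mass on the true class
#' (higher accuracy); at `quality = 0` scores hug the prior, so the
#' classifier effectively guesses the majority class.
#'
#' @param config a [simulation_config()] (or arguments to build one via
#'   `...` when `config` is missing).
#' @param ... passed to [simulation_config()] when `config` is missing.
#' @return list of class `"synthetic_cohort"` with `labels` (character
#'   vector), `score_tables` (list of [prob_matrix()]), and
#'   `realized_accuracies` (argmax accuracy of each table against the
#'   labels), plus the `config`.
#' @examples
#' coh <- simulate_cohort(simulation_config(n_samples = 200, seed = 42))
#' coh$realized_accuracies
#' @export
simulate_cohort <- function(config = simulation_config(...), ...) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_samples
  N <- length(config$class_prior)
  C <- config$n_classifiers
  rho <- config$correlation
  ids <- sprintf("s%04d", seq_len(n))

  y_idx <- sample.int(N, n, replace = TRUE, prob = config$class_prior)
  base_alpha <- .conc_scale * config$class_prior

  # per-class concentration matrix template (n x N), before quality boost
  alpha0 <- matrix(base_alpha, n, N, byrow = TRUE)
  boost <- matrix(0, n, N)
  boost[cbind(seq_len(n), y_idx)] <- 1

  # shared latent Gamma component uses the unboosted concentration so that
  # the correlation knob injects label-free common noise
  shared <- matrix(stats::rgamma(n * N, shape = alpha0), n, N)

  tables <- vector("list", C)
  for (c in seq_len(C)) {
    alpha_c <- alpha0 + config$quality[c] * boost
    own <- matrix(stats::rgamma(n * N, shape = alpha_c), n, N)
    w <- rho * shared + (1 - rho) * own
    p <- w / rowSums(w)
    # temperature scaling (miscalibration); argmax-preserving
    Tc <- config$miscalibration[c]
    if (Tc != 1) {
      p <- p^(1 / Tc)
      p <- p / rowSums(p)
    }
    tables[[c]] <- prob_matrix(p, sample_ids = ids,
                               class_labels = config$class_labels)
  }

  labels <- config$class_labels[y_idx]
  acc <- vapply(tables, function(t) {
    mean(colnames(t)[max.col(unclass(t), ties.method = "first")] == labels)
  }, numeric(1))

  structure(list(
    labels = stats::setNames(labels, ids),
    score_tables = tables,
    realized_accuracies = acc,
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d classes, %d classifiers\n",
              x$config$n_samples, length(x$config$class_prior),
              x$config$n_classifiers))
  cat("  label counts:\n")
  print(table(factor(x$labels, levels = x$config$class_labels)))
  cat("  realized accuracies:",
      paste(formatC(x$realized_accuracies, digits = 4, format = "f"),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated cohort as an on-disk fixture bundle
#'
#' Materialises a cohort as the file set the command-line interface
#' consumes: one delimited score table per classifier
#' (`scores_<k>.csv`), a labels file (`labels.csv`), and a JSON ensemble
#' manifest (`manifest.json`) whose accuracy entries are the realized
#' accuracies. Files round-trip through [read_score_table()] and
#' [read_manifest()].
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with the `cohort`, the `manifest`, and
#'   `manifest_path`.
#' @export
make_fixture_bundle <- function(config = simulation_config(), dir) {
  if (missing(dir)) stop("an output directory is required", call. = FALSE)
  cohort <- simulate_cohort(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)

  C <- config$n_classifiers
  entries <- vector("list", C)
  for (c in seq_len(C)) {
    path <- file.path(dir, sprintf("scores_%d.csv", c))
    write_score_table(cohort$score_tables[[c]], path)
    entries[[c]] <- list(id = sprintf("clf%d", c),
                         path = sprintf("scores_%d.csv", c),
                         accuracy = cohort$realized_accuracies[c])
  }
  labels_path <- file.path(dir, "labels.csv")
  write_labels(cohort$labels, labels_path)

  manifest <- list(
    classifiers = entries,
    labels = "labels.csv",
    positive_class = config$class_labels[length(config$class_labels)],
    options = list(accuracy_policy = "manifest"))
  manifest_path <- file.path(dir, "manifest.json")
  write_manifest(manifest, manifest_path)

  invisible(list(cohort = cohort, manifest = manifest,
                 manifest_path = manifest_path))
}
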